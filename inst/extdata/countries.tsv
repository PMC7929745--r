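alias	canonical	type
united states	United States	country
usa	United States	country
us	United States	country
u.s.	United States	country
u.s.a.	United States	country
america	United States	country
united states of america	United States	country
united kingdom	United Kingdom	country
uk	United Kingdom	country
u.k.	United Kingdom	country
great britain	United Kingdom	country
britain	United Kingdom	country
england	United Kingdom	country
germany	Germany	country
deutschland	Germany	country
netherlands	Netherlands	country
the netherlands	Netherlands	country
holland	Netherlands	country
nl	Netherlands	country
canada	Canada	country
france	France	country
australia	Australia	country
aus	Australia	country
india	India	country
spain	Spain	country
sweden	Sweden	country
japan	Japan	country
italy	Italy	country
singapore	Singapore	country
belgium	Belgium	country
switzerland	Switzerland	country
portugal	Portugal	country
afghanistan	Afghanistan	country
denmark	Denmark	country
czech republic	Czech Republic	country
czechia	Czech Republic	country
china	China	country
austria	Austria	country
poland	Poland	country
norway	Norway	country
finland	Finland	country
ireland	Ireland	country
mexico	Mexico	country
brazil	Brazil	country
colombia	Colombia	country
vietnam	Vietnam	country
thailand	Thailand	country
russia	Russia	country
new zealand	New Zealand	country
nz	New Zealand	country
south africa	South Africa	country
europe	Europe	region
eu	Europe	region
european union	Europe	region
worldwide	worldwide	region
world wide	worldwide	region
ww	worldwide	region
global	worldwide	region
anywhere	worldwide	region
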