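term	category	kind
gunpowder	Heroin	jargon
pearl tar (black pearl tar)	Heroin	jargon
speedball	Heroin	jargon
heroin #4	Heroin	jargon
diacetylmorphin	Heroin	jargon
h3 brown sugar	Heroin	jargon
chyna (china white)	Fentanyl	jargon
acetylfentanyl (acetyl fentanyl)	Fentanyl	jargon
phenaridine	Fentanyl	jargon
duragesic	Fentanyl	jargon
subutex	Buprenorphine	jargon
suboxone	Buprenorphine	jargon
roxy	Oxycodone	jargon
roxi	Oxycodone	jargon
roxies	Oxycodone	jargon
roxys	Oxycodone	jargon
oxynorm	Oxycodone	jargon
A215	Oxycodone	jargon
K8/K9	Oxycodone	jargon
M15/30	Oxycodone	jargon
blueberries	Oxycodone	jargon
A15	Oxycodone	jargon
OC30/80	Oxycodone	jargon
OP80	Oxycodone	jargon
oxyneo	Oxycodone	jargon
M523/IP204/C230	Oxycodone	jargon
bananas	Oxycodone	jargon
V4812	Oxycodone	jargon
CDN 80	Oxycodone	jargon
DHC	Dihydrocodeine	jargon
panda	Oxymorphone	jargon
o bomb	Oxymorphone	jargon
zomorph	Morphine	jargon
mscontin (ms contin)	Morphine	jargon
skenan	Morphine	jargon
oramorph	Morphine	jargon
kadian	Morphine	jargon
amidone	Methadone	jargon
methadose	Methadone	jargon
chocolate chip cookies	Methadone	jargon
hydromorph	Hydromorphone	jargon
lortab	Hydrocodone	jargon
norcos	Hydrocodone	jargon
zohydro	Hydrocodone	jargon
IP109/110	Hydrocodone	jargon
M367	Hydrocodone	jargon
UDT 200	Tramadol	jargon
thiocodin	Codeine	jargon
lean	Codeine	jargon
tapentadol	Others	jargon
tapalee	Others	jargon
nucynta	Others	jargon
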