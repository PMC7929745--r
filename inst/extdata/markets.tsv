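name	kind	open_date	close_date	measurement_start	measurement_end	n_records	n_opioid
Agora	marketplace	2013-12-01	2015-08-31	2014-01-01	2015-07-31	140266	12051
Alphabay	marketplace	2014-12-01	2017-07-31	2014-12-01	2015-07-31	21679	1344
Hydra	marketplace	2014-03-01	2014-11-30	2014-08-01	2014-10-31	3048	218
Pandora	marketplace	2013-10-01	2014-11-30	2013-12-01	2014-11-30	20013	1749
Evolution	marketplace	2014-01-01	2015-03-31	2014-04-01	2015-03-31	54196	4954
Apollon	marketplace	2018-05-01	2020-03-31	2018-09-01	2020-02-29	2921	2552
Empire	marketplace	2018-02-01	2020-08-31	2018-04-01	2020-03-31	2995	2548
The Versus Project	marketplace	2019-11-01		2019-11-01	2020-03-31	233	202
Avaris	marketplace	2019-10-01	2020-08-31	2019-10-01	2020-02-29	291	286
Darkbay	marketplace	2019-07-01	2020-09-30	2019-07-01	2020-02-29	2717	2112
Black Market	forum	2013-12-01	2014-02-28	2013-12-01	2014-02-28	52127	669
Pandora	forum	2013-10-01	2014-09-30	2014-01-01	2014-09-30	18640	798
Hydra	forum	2014-03-01	2014-11-30	2014-04-01	2014-09-30	887	41
The Hub	forum	2014-01-01		2014-01-01	2015-07-31	53973	1082
Evolution	forum	2014-01-01	2015-03-31	2014-01-01	2014-11-30	166641	2682
Silk Road	forum	2011-01-01	2014-11-30	2011-06-01	2013-11-30	846693	34519
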