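sample_id	taxon001	taxon002	taxon003	taxon004	taxon005	taxon006	taxon007	taxon008
sample001	0.132424965317351	0.41280104408407	0	0	0.026463137766696	0	0.428310852831884	0
sample002	0.00196886526327121	0.00464374760435299	0.480739107822854	0.486158239539751	0	0.0019980821905479	0	0.0244919575792234
sample003	0.0272164439689961	0.0378709336283881	0	0	0.921504369109713	1.16034010282906e-05	0.013396649891874	0
sample004	0.0550670782403319	0.0949675243297059	0	0	0.383125878121927	0	0.466839519308035	0
sample005	0.0635343002950103	0.0693598915202198	0.00177582788707081	0.00339717898262697	0.000725753007006811	0.847711296625247	0.00261322218227108	0.0108825295005476
sample006	0.226864377730408	0.226921677453125	0.000380643612413271	0.00106225348678867	0.00495402801537016	0.46537270581413	0.0596160407911917	0.0148282730965734
sample007	0.00213101110715912	0.00367942540511291	0.0033977493467845	0.00365165510486214	2.85977541410521e-06	0.983536168059312	0	0.0036011312013547
sample008	0.0197706442374628	0.0472537155921421	0	0	0.794346662774907	0	0.138628977395488	0
sample009	0.351340717889614	0.369844684164517	0.0188377824894349	0.063512836775768	0.132906617271451	0.0016493247327539	0.0544506665595294	0.00745737011693141
sample010	0.00523227720563337	0.0185596294388745	0.24722267497728	0.406957177441863	0	0.0410738066546393	0	0.28095443428171
sample011	0.392295546887232	0.421976900928671	3.82212213447468e-05	0.000133063089357401	0.172280970035868	0.000319365232561966	0.0123459171410238	0.000610015463941505
sample012	0.211865626331862	0.249448828930173	0.0116355669957808	0.0191619333493548	0.000189054641501318	0.501865277806519	0.00327411843793608	0.00255959350687276
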