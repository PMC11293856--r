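sample_id	temperature	salinity	nitrate	silicate
sample001	9.31554503256855	34.6293375018425	21.4824901638724	22.9860003257251
sample002	23.6768780989889	35.2302958373211	7.89367347714241	5.54046458599493
sample003	14.0224080044745	35.0038244845583	11.7774566019396	17.2923539825966
sample004	12.8451288257037	35.1217621637186	17.4306605431797	20.6249478139862
sample005	19.0824511070367	35.2628383996516	10.0084914408039	19.1587682113954
sample006	17.3251979196646	35.2584299196311	6.78049090307665	19.3636316387717
sample007	21.9879422600964	35.009996889302	5.96984142811418	17.4567266859744
sample008	11.0733574294228	35.0473937575782	17.8082256269123	27.2138700099592
sample009	16.1448195548383	35.173975485509	12.2036424188786	18.6931549118996
sample010	26.681952011953	35.4303806406357	1.93086318741258	7.00219318327007
sample011	15.8955257504974	35.5519729264529	13.155283085843	17.247833855889
sample012	19.7216143456408	35.3908246252596	9.2866056385327	11.8594981696511
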