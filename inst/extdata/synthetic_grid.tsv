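lat	lon	temperature	salinity	nitrate	silicate
-65	-175	9.03320396463839	35.0012491418513	16.6676098071666	32.4179369512663
-55	-175	11.7835416558316	35.4095658430435	17.4990442045803	21.0878554163649
-45	-175	15.2584648140773	34.6323192372145	16.0542035354754	14.2700225399705
-35	-175	17.9223949701708	34.9074367731704	10.6144780354755	16.8300484750016
-25	-175	21.4363068984283	35.0341900877698	5.9256157514697	11.1639419958856
-15	-175	22.6131274750328	35.4159878748454	10.3572553845167	7.19132074469197
-5	-175	27.7919869075835	34.9792387994706	3.69795563386892	6.08137975485364
5	-175	26.5818096571017	35.3950827960934	3.85260389893544	12.2427515491222
15	-175	23.5519154023303	34.5229923776271	5.74241610336481	12.9916143545237
25	-175	20.6370631092348	34.9283745326613	11.6708279339135	14.3730950084345
35	-175	19.4775705482675	34.9260649203272	10.0351846514255	18.5614948265657
45	-175	14.9311028530207	35.3412945783368	14.0142996836134	9.05508377200941
55	-175	12.6710541016949	35.2044676261932	14.8668794096648	16.4176547618249
65	-175	9.53396155024773	34.879334249585	20.5395539142617	26.372825731553
-65	-115	11.6452571952764	34.4830700535459	13.8918256899433	22.6094060458831
-55	-115	11.7605503425472	34.7367509529601	18.0357320633333	26.5034372916226
-45	-115	15.3225519413638	34.9905279545849	16.258469354558	20.8641234825159
-35	-115	15.5822944737326	34.8672707845732	13.3614717166531	25.3708189423402
-25	-115	21.8878840258161	35.3496090371244	10.5412384691051	9.94382438226894
-15	-115	23.0925085537023	34.59991709035	5.67435326392323	11.9023714066197
-5	-115	28.3569929403275	34.8094704643858	5.38478272038496	12.1827143274752
5	-115	26.7822521432025	35.1457248088667	3.57572096414587	14.231857763113
15	-115	23.5331112547864	35.3246869516316	7.95239273804448	10.3708903303603
25	-115	21.9264216312476	35.1217908174811	5.42446344396245	21.12081905507
35	-115	17.5066681228072	34.6877738483223	10.6219777384274	10.8760799659922
45	-115	18.0819900697093	35.4860314461241	12.8147904731715	20.7186134696177
55	-115	12.8225244801558	34.9726982127388	16.5527964881089	24.5869576817452
65	-115	9.0933275884407	34.2722824357821	19.5158842117916	25.8792139052187
-65	-55	10.2172132457699	35.0332684922146	19.4657573543069	20.0488279959111
-55	-55	12.9695567781549	35.1581885484275	15.9320080554088	22.7584212507311
-45	-55	14.4862356505866	35.2075755797779	16.8957381519987	26.7362932406168
-35	-55	17.8830852546865	34.8858521249438	8.0936324022422	14.6878674939579
-25	-55	22.0490592053062	35.138495280371	6.35575742090207	23.4821498817945
-15	-55	23.9681118065356	35.1516691189057	6.35060844245061	12.7080790598059
-5	-55	26.6314402115034	35.3059922852755	6.62187793391864	7.31001110316526
5	-55	25.5896694606253	35.0749532529763	6.58620127366542	11.7002585812832
15	-55	24.1827515323825	35.3537280472446	9.92201920541531	10.4934954928775
25	-55	20.1803034744632	35.3317209667399	9.90364296147205	10.6685108909759
35	-55	18.5617110942998	35.1825843424315	11.7215505963297	17.6347694148957
45	-55	15.4933713631495	34.7777054112875	16.8007690633968	19.0100869474621
55	-55	11.7915436558675	35.553816731774	16.3985538074538	16.191729038153
65	-55	7.78061830560158	35.3399699892223	18.6391254546963	29.0839009757401
-65	5	9.06127592756933	34.6310337230451	21.685045265674	25.0735583944906
-55	5	12.9828865608579	35.3735673048451	18.6740382086962	19.7535015393085
-45	5	17.1308636675747	35.4426037971748	13.5072690070502	19.7763081048915
-35	5	17.9969180492753	34.9013693038223	14.9648650820323	20.6555093060182
-25	5	20.0036026524754	34.8839012287862	11.9278662157142	21.8117459375276
-15	5	22.4934637053786	34.6358010721991	4.25567632050766	13.0045004810531
-5	5	25.6021683960996	35.2370136904335	8.36676990258544	9.95000390322067
5	5	26.0349712736169	35.026138239459	6.02090006697587	18.6929446160599
15	5	25.5520578358682	35.5628336370019	2.21506344307773	15.5001476838666
25	5	20.4522286484067	34.8203628510192	6.74907541422898	18.0820654216018
35	5	17.3414742920221	34.4483257533265	10.4815967396414	19.3665714280864
45	5	15.4492945332041	34.7802481554143	14.7955735734365	21.3336140451372
55	5	12.3999555181942	35.547566638814	16.3520459360888	21.4104753655565
65	5	8.69604555099477	35.175202005804	20.9134878344205	31.5425074980235
-65	65	10.0405880381501	34.3986979565077	20.9149437422442	22.9062230490644
-55	65	12.9811136157033	34.885778656116	17.9459137452948	20.5977957222904
-45	65	17.6304589495847	35.4695552317701	6.91313652248675	16.6946087293813
-35	65	19.3992023920509	34.4479167412175	9.71489519063026	19.011887326768
-25	65	21.2812222267155	34.4156018766491	6.19015180131574	11.54289989051
-15	65	22.5972913736975	34.8021241014149	10.1618548412318	11.0261337878882
-5	65	27.0651636909237	35.4298109327272	5.57744187338137	15.7646648910004
5	65	26.9520163857755	34.8018318037623	3.9039944227468	2.1965160301539
15	65	23.2101437829189	35.3769821419295	9.20969339803754	17.2010652064729
25	65	20.1464000409127	35.2327254420212	7.09959845953484	16.3714269889425
35	65	17.9532678804406	35.2092778429147	10.8186861593455	24.3107199461121
45	65	16.9393385707086	34.8621155099947	11.064574211843	23.8441598902567
55	65	13.1460776836671	35.0257404108453	15.2933898229526	19.0575063888515
65	65	11.364961850708	35.4051317943303	17.0391998772551	22.4766161353374
-65	125	10.0496701779971	35.1606232193172	19.3601672037252	13.8481915082664
-55	125	10.6375813698812	35.0351755271145	20.0821137077869	22.4047882480948
-45	125	14.5909397771317	35.1340830426472	15.4118985390938	23.6383978610409
-35	125	17.7013149121829	35.3178627617794	12.4316262403663	16.4383742778847
-25	125	21.3051217688043	35.8287586789849	8.90898434312705	11.1240088193178
-15	125	23.5107927580015	34.6607468366305	7.18589762455954	15.8498625933312
-5	125	28.0577142007869	35.1299640691684	6.67954263889428	9.0068890320154
5	125	27.4737554835971	35.1792161862156	3.21831338476267	14.3179047519978
15	125	22.8470439583732	34.9262841203452	6.25428919025712	10.246974670022
25	125	20.9683245240361	34.9876041820719	10.1177378627115	6.45056019835673
35	125	18.3140758739445	35.0737412690429	14.7085534522996	15.8508252194957
45	125	14.3463401191528	34.8996562369996	16.1055173657752	19.2009526329806
55	125	12.7559991454717	34.8460810564972	16.0902344354264	20.6845675765429
65	125	11.1003942137063	34.8278719137494	13.1215326274464	24.6882893903421
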