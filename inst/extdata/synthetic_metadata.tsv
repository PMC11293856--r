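sample_id	latitude	longitude	depth	month	size_fraction
sample001	63.5582087212242	98.2123004738241	10	6	20-180
sample002	-13.2930910727009	-145.331445001066	10	6	0.22-3
sample003	-49.9592887610197	-16.7588027659804	10	11	20-180
sample004	-55.9326717676595	-149.507743343711	10	5	0.8-2000
sample005	-33.3125792234205	21.8397121410817	10	4	0.22-3
sample006	37.9613553569652	-176.866344027221	10	11	20-180
sample007	-20.7918941322714	174.865352651104	10	6	0.22-3
sample008	61.3681250857189	-66.029470525682	10	10	0.22-3
sample009	-43.4387870086357	50.2016190905124	10	7	0.22-3
sample010	-5.31652344856411	-73.7196352612227	10	2	0.22-3
sample011	-42.6727500162087	178.813329795375	10	4	0.8-2000
sample012	-34.9079767661169	146.167675293982	10	6	0.22-3
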