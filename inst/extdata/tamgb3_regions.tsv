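region_id	contig_length	contig_start	contig_end	ref_start	ref_end	ref_length	gap
tamGB3	2800262	1	2800262	597594329	609618385	12024056	9484375
Region 1	12509	483735	496244	599644736	599701494	56758	45368
Region 2	62528	1507758	1570286	604381862	604643416	261554	205897
Region 3	39968	2621288	2661256	608922872	609104595	181723	145529
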