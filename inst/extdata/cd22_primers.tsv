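name	start	end	description
P7	2180	2361	Exon 11 to Exon 13 amplicon spanning Exon 12
P9	2304	2463	Exon 12 to Exon 14 amplicon spanning Exon 13
P10	433	645	Exon 4 control amplicon present in both transcripts
exon12_deletion	2208	2327	cDNA bases removed by exon 12 skipping
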