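species	genus_median	refseq_accession	refseq_length	refseq_published	alt_accession	alt_length	alt_published
Angelica sinensis	146962	NC_042826	142485	2019-06-25	MW820164	146952	2021-09-05
Ficus auriculata	160363	NC_053837	162558	2021-03-26	MZ662866	160361	2022-08-31
Fragaria mandshurica	155621	NC_018767	129805	2012-10-14	MW537846	155640	2022-03-30
Fragaria vesca	155621	NC_018766	129788	2012-10-14	KC507757	155620	2016-07-26
Vitis romanetii	160971	NC_056348	232020	2021-06-20	MW592524	160976	2022-03-16
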