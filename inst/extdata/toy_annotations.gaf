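!gaf-version: 2.1
!synthetic annotations for parser tests
SGD	YAL001C	YAL001C		GO:0006996	PMID:1	IEA		P			gene_product	taxon:4932	20120326	SGD
SGD	YBL002W	YBL002W		GO:0016043	PMID:1	IEA		P			gene_product	taxon:4932	20120326	SGD
SGD	YCL003W	YCL003W		GO:0051179	PMID:1	IEA		P			gene_product	taxon:4932	20120326	SGD
SGD	YDL004W	YDL004W		GO:0009987	PMID:1	IEA		P			gene_product	taxon:4932	20120326	SGD
SGD	YAL001C	YAL001C		GO:0005215	PMID:1	IEA		F			gene_product	taxon:4932	20120326	SGD
SGD	YZZ999W	YZZ999W		GO:9999999	PMID:1	IEA		P			gene_product	taxon:4932	20120326	SGD
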