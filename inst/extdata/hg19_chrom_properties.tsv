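# hg19 chromosome lengths (UCSC) and protein-coding gene densities
# (genes per sequenced Mb), compiled from standard annotation summaries.
chrom	gene_density	length_bp
chr1	8.3	249250621
chr2	5.1	243199373
chr3	5.3	198022430
chr4	4.0	191154276
chr5	4.9	180915260
chr6	5.9	171115067
chr7	5.7	159138663
chr8	4.7	146364022
chr9	5.5	141213431
chr10	5.4	135534747
chr11	9.5	135006516
chr12	7.7	133851895
chr13	2.8	115169878
chr14	5.7	107349540
chr15	5.9	102531392
chr16	9.6	90354753
chr17	14.6	81195210
chr18	3.4	78077248
chr19	23.9	59128983
chr20	8.7	63025520
chr21	4.9	48129895
chr22	9.7	51304566
chrX	5.4	155270560
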