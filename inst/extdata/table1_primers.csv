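# qPCR assay metadata for the 14 candidate reference genes and the CYP72A1 validation target.
# The source publishes each primer pair as one concatenated forward+reverse string;
# the forward/reverse split below is a midpoint approximation and enters no computation.
# Amplicon length (bp), amplification efficiency E and standard-curve R2 are exact transcriptions.
gene_name,gene_id,gene_symbol,arabidopsis_locus,forward_primer,reverse_primer,amplicon_bp,efficiency,r_squared,is_candidate_reference
Glyceraldehyde-3-phosphate dehydrogenase,CL7040.Contig2_All,GAPDH,AT1G13440,AAATTAAGGCTGCAATCAAGC,AAGCCACAAGCTTCACAAAGT,169,1.874,0.9992,TRUE
Actin,CL1144.Contig2_All,ACT,AT3G18780,CAAATCATGTTCGAGACCTTC,AAGACGAAGAATGGCATGGGGA,173,1.873,0.9989,TRUE
Ubiquitin-conjugating enzyme,CL5627.Contig8_All,UBC,AT4G27960,TGCCTTGACCATCTCCAAGGTT,CTCAACTATCCATCCGCTCACCC,200,1.865,0.9995,TRUE
Elongation factor 1-alpha,CL3597.Contig3_All,EF1-alpha,AT1G07920,AAGGATGGGCAGACCCGTGAGC,ACCAACCTTCTTGAGGTAGGAAG,161,1.823,0.9991,TRUE
alpha-tubulin,CL544.Contig2_All,alpha-TUB,AT1G50010,TGTGCATTGGTATGTTGGTGA,GTCATCCCCCTCGTCACCCTC,139,1.872,0.9994,TRUE
beta-tubulin,Unigene13345_All,beta-TUB,AT5G12250,TATCAACAGTATCAGGATGCGA,CCGAACAATCAAAACCACCATAA,213,1.853,0.9995,TRUE
Serine/threonine-protein phosphatase PP2A,CL6570.Contig3_All,PP2A,AT1G13320,GTACCGAACATTAAATTCAAT,CTTGATTTGCAAAATATCTGAC,176,1.863,0.9994,TRUE
Expressed protein 1,CL7794.Contig1_All,EXP1,AT2G32170,ATTGAAACAACCTACACCGCAA,GCTGTAAGAATGCTAATCGTTCA,133,1.872,0.9995,TRUE
Polypyrimidine tract-binding protein 1,CL6418.Contig1_All,PTBP1,AT3G01150,GCAATTTTTGAGAAGAATGGTG,GACAGATGAAGCTTACAGTAAC,131,1.876,0.9996,TRUE
Expressed protein 2,CL670.Contig8_All,EXP2,AT4G33380,AAACATCAAGAGTGCTGGCT,TGCATGCATAGAGTGATTAC,198,1.779,0.9996,TRUE
TIP41-like protein,Unigene3100_All,TIP41,AT4G34270,GCAACCATCCAAAGTTTAACTGC,TAATGTGCAAGCAGGGCTAGTAA,157,1.847,0.9996,TRUE
Cyclophilin 1,CL6321.Contig1_All,CYP1,AT2G16600,TCGTGAGGGCCATCGAGAAGGT,CTCATAACAAACAGACCATTATT,137,1.819,0.9997,TRUE
Cyclophilin 2,CL8032.Contig1_All,CYP2,AT4G33060,TCCCGATTCTTCTGGAAAGGA,AGCCTTGTCTGGTAGAACAGC,181,1.880,0.9996,TRUE
mitosis protein YLS8,CL7523.Contig2_All,YLS8,AT5G08290,CGACTGGGACGAAACCTGCATG,CGGATCGTACGCTCGTACATTG,138,1.775,0.9996,TRUE
secologanin synthase,CL4267.Contig5_All,CYP72A1,AT3G14690,TTCACTCTCCCTTCTCCTTT,AGCACCGATTTCCTCTTTCAT,150,1.820,0.9996,FALSE
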