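gene,guide,genomic_places,n_places,n_snps,snp_details,bp_in_loops,at_percent,efficiency,assay,source,low_efficiency
PVALB,ATTGGGTGTTCAGGGCAGAG,chr22:37196884-37196906(+),1,1,rs12483924 (2 bp to 3' end),6,45,6.50%,Surveyor,Cong et al. 2013,FALSE
PVALB,GTGGCGAGAGGGGCCGAGAT,chr22:37196866-37196888(+),1,3,rs3484 (18 bp to 3' end);rs181855770 (10 bp to 3' end);rs9607383 (9 bp to 3' end),9,30,ND,Surveyor,Cong et al. 2013,TRUE
PVALB,GGGGCCGAGATTGGGTGTTC,chr22:37196875-37196897(+),1,2,rs181855770 (19 bp to 3' end);rs9607383 (18 bp to 3' end),9,35,ND,Surveyor,Cong et al. 2013,TRUE
AAVS1,GGGGCCACTAGGGACAGGAT,chr19:55627117-55627139(-),1,0,,8,35,8.07%,HR,Mali et al. 2013,FALSE
AAVS1,GTCCCCTCCACCCCACAGTG,chr19:55627136-55627158(-);chr4:108975634-108975656(+),2,0,rs115503552 (7 bp to 3' end) at off-target site,7,30,3.26%,HR,Mali et al. 2013,TRUE
VEGFA,GGGTGGGGGGAGTTTGCTCC,chr6:43737291-43737313(-),1,1,rs12210204 (1 bp to 3' end),11,30,26%,T7EI,Fu et al. 2013,TRUE
VEGFA,GACCCCCTCCACCCCGCCTC,chr6:43738556-43738578(-),1,0,,4,20,50%,T7EI,Fu et al. 2013,FALSE
VEGFA,GGTGAGTGAGTGTGTGCGTG,chr6:43737454-43737476(+),1,0,,12,40,49.40%,T7EI,Fu et al. 2013,FALSE
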