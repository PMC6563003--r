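version: canfam3.1-morphology-1
registry:
  35A: 12C9A2G12A
  35B: 11C10A2G12A
  33C: 10C9A2G12A
  31A: 10C8A2G11A
sites:
- site_id: MC1R_ginger
  chromosome: '5'
  position: 63694334
  gene: MC1R
  locus_code: E
  variant_class: SNV
  reference_allele: G
  alternate_alleles:
  - A
  phenotype_allele: A
  inheritance: recessive
  phene_label: Ginger (p.R306*)
  omia_code: 001199-9615
- site_id: MC1R_mask
  chromosome: '5'
  position: 63694460
  gene: MC1R
  locus_code: E
  variant_class: SNV
  reference_allele: C
  alternate_alleles:
  - T
  phenotype_allele: C
  inheritance: dominant
  phene_label: Melanistic mask (p.M264V); mask allele is the reference C
  omia_code: 001590-9615
- site_id: TYRP1_C41S
  chromosome: '11'
  position: 33317810
  gene: TYRP1
  locus_code: B
  variant_class: SNV
  reference_allele: T
  alternate_alleles:
  - C
  phenotype_allele: C
  inheritance: recessive
  phene_label: Brown (p.C41S)
  omia_code: 001249-9615
- site_id: TYRP1_Y185X
  chromosome: '11'
  position: 33319349
  gene: TYRP1
  locus_code: B
  variant_class: SNV
  reference_allele: T
  alternate_alleles:
  - G
  phenotype_allele: G
  inheritance: recessive
  phene_label: Brown (p.Tyr185*)
  omia_code: 001249-9615
- site_id: TYRP1_Q331X
  chromosome: '11'
  position: 33326685
  gene: TYRP1
  locus_code: B
  variant_class: SNV
  reference_allele: C
  alternate_alleles:
  - T
  phenotype_allele: T
  inheritance: recessive
  phene_label: Brown (p.Q331X)
  omia_code: 001249-9615
- site_id: TYRP1_345delP
  chromosome: '11'
  position: 33326727
  end_position: 33326729
  gene: TYRP1
  locus_code: B
  variant_class: indel
  reference_allele: ins
  alternate_alleles:
  - del
  phenotype_allele: del
  inheritance: recessive
  phene_label: Brown (p.345delP)
  omia_code: 001249-9615
- site_id: CBD103_K
  chromosome: '16'
  position: 58965449
  end_position: 58965451
  gene: CBD103
  locus_code: K
  variant_class: indel
  reference_allele: ins
  alternate_alleles:
  - del
  phenotype_allele: del
  inheritance: dominant
  phene_label: Black (dominant); the insertion (reference) permits A-locus colors
  omia_code: 001416-9613
- site_id: MITF_SINE
  chromosome: '20'
  position: 21836232
  end_position: 21836427
  gene: MITF
  locus_code: S
  variant_class: SINE_insertion
  reference_allele: ins
  alternate_alleles:
  - del
  phenotype_allele: ins
  inheritance: recessive
  phene_label: SINE insertion associated with piebald/extreme white
  omia_code: 000214-9615
- site_id: MITF_length
  chromosome: '20'
  position: 21839321
  end_position: 21839366
  gene: MITF
  locus_code: S
  variant_class: length_polymorphism
  reference_allele: 12C9A2G12A
  alternate_alleles:
  - 11C10A2G12A
  - 10C9A2G12A
  - 10C8A2G11A
  phenotype_allele: 12C9A2G12A
  inheritance: codominant
  phene_label: Promoter length polymorphism; longer alleles give more white
  omia_code: 000214-9615
- site_id: RALY_dup
  chromosome: '24'
  position: 23252754
  end_position: 23252770
  gene: RALY
  locus_code: A
  variant_class: indel
  reference_allele: del
  alternate_alleles:
  - ins
  phenotype_allele: ins
  inheritance: recessive
  phene_label: '16-bp duplication (dupCCCCAGGTCAGAGTTT): at is ins/ins, saddle as
    is del-'
  omia_code: 001806-9615
- site_id: ASIP_ins239
  chromosome: '24'
  position: 23365298
  gene: ASIP
  locus_code: A
  variant_class: indel
  reference_allele: del
  alternate_alleles:
  - ins
  phenotype_allele: ins
  inheritance: recessive
  phene_label: '239-base insertion: at is ins/ins, Ay is del-'
  omia_code: 000201-9615
- site_id: ASIP_A82
  chromosome: '24'
  position: 23393510
  gene: ASIP
  locus_code: A
  variant_class: SNV
  reference_allele: T
  alternate_alleles:
  - G
  phenotype_allele: T
  inheritance: dominant
  phene_label: 'Sable/fawn: Ay carries the reference T'
  omia_code: 000201-9615
- site_id: ASIP_R83
  chromosome: '24'
  position: 23393514
  gene: ASIP
  locus_code: A
  variant_class: SNV
  reference_allele: A
  alternate_alleles:
  - G
  phenotype_allele: A
  inheritance: dominant
  phene_label: 'Sable/fawn: Ay carries the reference A'
  omia_code: 000201-9615
- site_id: ASIP_R92
  chromosome: '24'
  position: 23393552
  gene: ASIP
  locus_code: A
  variant_class: SNV
  reference_allele: C
  alternate_alleles:
  - T
  phenotype_allele: T
  inheritance: recessive
  phene_label: Recessive black (a is T/T)
  omia_code: 000201-9615
- site_id: MSRB3_UTR_ins
  chromosome: '10'
  position: 8038433
  gene: MSRB3_UTR
  locus_code: EAR
  variant_class: indel
  reference_allele: del
  alternate_alleles:
  - insTTTATTTTAT
  - insTTTAT
  phenotype_allele: del
  inheritance: recessive
  phene_label: 3'UTR insertion polymorphism; drop ears are del/del
- site_id: MSRB3_HMGA2_SNP
  chromosome: '10'
  position: 8085469
  gene: MSRB3_HMGA2_intergenic
  locus_code: EAR
  variant_class: SNV
  reference_allele: C
  alternate_alleles:
  - T
  phenotype_allele: C
  inheritance: recessive
  phene_label: Intergenic ear SNP; drop ears are C/C
  omia_code: 000319-9615
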