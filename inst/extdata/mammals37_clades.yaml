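# Species set and clade structure for the 37-mammal ortholog alignments.
# Species are identified by genome-assembly codes (UCSC style).
# major_clades tags: pri Primates; eua non-primate Euarchontoglires;
# lau Laurasiatheria; afr Afrotheria; xen Xenarthra; met Metatheria;
# pro Prototheria.
reference: hg19
major_clades:
  pri: [hg19, panTro2, gorGor1, ponAbe2, nomLeu1, rheMac2, papHam1,
        calJac1, tarSyr1, micMur1, otoGar1]
  eua: [tupBel1, mm9, rn4, dipOrd1, cavPor3, speTri1, oryCun2, ochPri2]
  lau: [canFam2, felCat3, equCab2, bosTau4, turTru1, vicPac1, pteVam1,
        myoLuc1, eriEur1, sorAra1]
  afr: [loxAfr3, proCap1, echTel1]
  xen: [dasNov2, choHof1]
  met: [monDom5, macEug1]
  pro: [ornAna1]
# Nested clade ladder on the human lineage, smallest first.  Each clade
# corresponds to one datable branch of the species tree.
ladder:
  - name: human
    members: [hg19]
  - name: human_chimp
    members: [hg19, panTro2]
  - name: african_great_apes
    members: [hg19, panTro2, gorGor1]
  - name: great_apes
    members: [hg19, panTro2, gorGor1, ponAbe2]
  - name: apes
    members: [hg19, panTro2, gorGor1, ponAbe2, nomLeu1]
  - name: catarrhines
    members: [hg19, panTro2, gorGor1, ponAbe2, nomLeu1, rheMac2, papHam1]
  - name: simians
    members: [hg19, panTro2, gorGor1, ponAbe2, nomLeu1, rheMac2, papHam1,
              calJac1]
  - name: haplorhines
    members: [hg19, panTro2, gorGor1, ponAbe2, nomLeu1, rheMac2, papHam1,
              calJac1, tarSyr1]
  - name: primates
    members: [hg19, panTro2, gorGor1, ponAbe2, nomLeu1, rheMac2, papHam1,
              calJac1, tarSyr1, micMur1, otoGar1]
species_names:
  hg19: human
  panTro2: chimpanzee
  gorGor1: gorilla
  ponAbe2: orangutan
  nomLeu1: gibbon
  rheMac2: rhesus
  papHam1: baboon
  calJac1: marmoset
  tarSyr1: tarsier
  micMur1: mouse_lemur
  otoGar1: bushbaby
  tupBel1: treeshrew
  mm9: mouse
  rn4: rat
  dipOrd1: kangaroo_rat
  cavPor3: guinea_pig
  speTri1: squirrel
  oryCun2: rabbit
  ochPri2: pika
  canFam2: dog
  felCat3: cat
  equCab2: horse
  bosTau4: cow
  turTru1: dolphin
  vicPac1: alpaca
  pteVam1: megabat
  myoLuc1: microbat
  eriEur1: hedgehog
  sorAra1: shrew
  loxAfr3: elephant
  proCap1: rock_hyrax
  echTel1: tenrec
  dasNov2: armadillo
  choHof1: sloth
  monDom5: opossum
  macEug1: wallaby
  ornAna1: platypus
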