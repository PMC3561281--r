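((((((((((((hg19,panTro2),gorGor1),ponAbe2),nomLeu1),(rheMac2,papHam1)),calJac1),tarSyr1),(micMur1,otoGar1)),tupBel1),(((mm9,rn4),dipOrd1),((cavPor3,speTri1),(oryCun2,ochPri2)))),((((canFam2,felCat3),(equCab2,((bosTau4,turTru1),vicPac1))),(pteVam1,myoLuc1)),(eriEur1,sorAra1))),((((loxAfr3,proCap1),echTel1),(dasNov2,choHof1)),((monDom5,macEug1),ornAna1)));
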