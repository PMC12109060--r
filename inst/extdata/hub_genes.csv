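subtype,direction,gene
LaBC,up,PIK3R1
LaBC,up,PIK3CA
LaBC,up,EGFR
LaBC,up,KIT
LaBC,up,PDGFRA
LaBC,up,FGFR1
LaBC,up,MET
LaBC,up,INSR
LaBC,down,STAT3
LaBC,down,ESR1
LaBC,down,MMP9
LaBC,down,MAPK1
LaBC,down,HSP90AB1
LaBC,down,NFKB1
LaBC,down,PIK3CA
LaBC,down,IGF1R
LbBC,up,EGFR
LbBC,up,PIK3CA
LbBC,up,PIK3R1
LbBC,up,KIT
LbBC,up,ALB
LbBC,up,BCL2
LbBC,up,APP
LbBC,up,PDGFRA
LbBC,down,AKT1
LbBC,down,ESR1
LbBC,down,MMP9
LbBC,down,STAT1
LbBC,down,HSP90AB1
LbBC,down,MAPK1
LbBC,down,GSK3B
Her2BC,up,EGFR
Her2BC,up,PIK3R1
Her2BC,up,PIK3CA
Her2BC,up,ESR1
Her2BC,up,IGF1R
Her2BC,up,BCL2
Her2BC,up,INSR
Her2BC,up,PDGFRA
Her2BC,down,AKT1
Her2BC,down,STAT1
Her2BC,down,MMP9
Her2BC,down,MAPK1
Her2BC,down,GSK3B
Her2BC,down,HSP90AB1
Her2BC,down,PTPN11
Her2BC,down,CDK1
TNBC,up,PIK3CA
TNBC,up,PIK3R1
TNBC,up,ESR1
TNBC,up,IGF1R
TNBC,up,KIT
TNBC,up,BCL2
TNBC,up,MME
TNBC,up,INSR
TNBC,down,STAT3
TNBC,down,SRC
TNBC,down,HSP90AB1
TNBC,down,STAT1
TNBC,down,GSK3B
TNBC,down,MAPK1
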