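# Default monomer library for polyester can-coating screening.
# One record per monomer: id, abbreviation, name, Hill formula of the free
# monomer, functional class (diacid/triacid/diol/triol/monool/hydroxyacid),
# aromatic flag. Acid isomers (PA/IPA/TPA) and diol isomers (BD/BD13/MPO)
# are isobaric on purpose: compositions keep them distinct, masses collapse.
# This default is an approximation of a typical coating formulary (the full
# industrial list of 19 polyols / 6 polyacids is not public); extend it by
# editing a copy of this file and loading it with load_monomer_library().
id,abbreviation,name,formula,monomer_class,aromatic
PA,PA,phthalic acid,C8H6O4,diacid,TRUE
IPA,IPA,isophthalic acid,C8H6O4,diacid,TRUE
TPA,TPA,terephthalic acid,C8H6O4,diacid,TRUE
AA,AA,adipic acid,C6H10O4,diacid,FALSE
TMA,TMA,trimellitic acid,C9H6O6,triacid,TRUE
NPG,NPG,neopentyl glycol,C5H12O2,diol,FALSE
HD,HD,"1,6-hexanediol",C6H14O2,diol,FALSE
BD,BD,"1,4-butanediol",C4H10O2,diol,FALSE
BD13,BD13,"1,3-butanediol",C4H10O2,diol,FALSE
MPO,MPO,"2-methyl-1,3-propanediol",C4H10O2,diol,FALSE
CHDM,CHDM,"1,4-cyclohexanedimethanol",C8H16O2,diol,FALSE
EG,EG,ethylene glycol,C2H6O2,diol,FALSE
DEG,DEG,diethylene glycol,C4H10O3,diol,FALSE
PD,PD,"1,3-propanediol",C3H8O2,diol,FALSE
GLY,GLY,glycerol,C3H8O3,triol,FALSE
TMP,TMP,trimethylolpropane,C6H14O3,triol,FALSE
CL,CL,"6-hydroxyhexanoic acid (ring-opened caprolactone)",C6H12O3,hydroxyacid,FALSE
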