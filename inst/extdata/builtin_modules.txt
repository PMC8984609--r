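# Shipped module catalog: metabolic gene sets for genome-centric profiling
# of seaweed phycosphere communities. Step decompositions for the KEGG-id
# modules follow canonical KO content; CUST_* entries are curated
# reconstructions from published gene lists. Identifiers are KO numbers or
# gene symbols; see builtin_aliases() for symbol -> K-number mapping.

# ---- carbon fixation -------------------------------------------------

MODULE M00165 carbon_fixation Calvin-Benson-Bassham (CBB) cycle
STEP K00855
STEP K01601+K01602
STEP K00927
STEP K00134,K05298
STEP K01623,K01624
STEP K03841,K02446,K11532
STEP K00615
STEP K01783
STEP K01807,K01808
KEY K01601+K01602
KEY K00855

MODULE M00173 carbon_fixation Reductive citric acid (rTCA) cycle
STEP K15230+K15231
STEP K00174+K00175
STEP K01959+K01960
STEP K00024
STEP K01676,K01679
STEP K18556+K18557,K00239+K00240+K00241
STEP K01902+K01903
STEP K00031
KEY K15230+K15231

MODULE M00375 carbon_fixation 3-Hydroxypropionate/4-hydroxybutyrate (HP-HB) cycle
STEP K01964+K15037+K15036
STEP K15017
STEP K15039
STEP K15018
STEP K15019
STEP K15020
STEP K14534
KEY K14534

MODULE M00376 carbon_fixation 3-Hydroxypropionate (3-HP) bicycle
STEP K02160+K01961+K01962+K01963
STEP K14468
STEP K14469
STEP K15052
STEP K05606
STEP K01847,K01848+K01849
KEY K14468

MODULE M00374 carbon_fixation Dicarboxylate/4-hydroxybutyrate (DC-HB) cycle
STEP K00169+K00170+K00171+K00172
STEP K01007
STEP K01595
STEP K00024
STEP K01676,K01679
STEP K18556+K18557,K00239+K00240+K00241
STEP K01902+K01903
STEP K15038
STEP K14534
KEY K14534

MODULE M00377 carbon_fixation Wood-Ljungdahl (reductive acetyl-CoA) pathway
STEP K00198
STEP K14138
STEP K00194
STEP K00197
STEP K01938
STEP K01491
STEP K00297
KEY K00198+K14138

# ---- nitrogen --------------------------------------------------------

MODULE CUST_ANRA nitrogen Assimilatory nitrate reduction to ammonium
STEP nasA,narB
STEP nirA
KEY nasA,narB
KEY nirA

MODULE CUST_DNRA nitrogen Dissimilatory nitrate reduction to ammonium
STEP narG+narH+narI,napA+napB
STEP nirB+nirD,nrfA+nrfH
KEY narG+narH+narI,napA+napB

MODULE CUST_DENITRIFICATION nitrogen Denitrification (nitrate to dinitrogen)
STEP narG+narH+narI,napA+napB
STEP nirK,nirS
STEP norB+norC
STEP nosZ
KEY nirK,nirS

MODULE CUST_NITRIFICATION nitrogen Nitrification (ammonia and nitrite oxidation)
STEP amoA+amoB+amoC
STEP nxrA+nxrB
KEY amoA+amoB+amoC

MODULE CUST_NFIX nitrogen Nitrogen fixation (nitrogenase)
STEP nifH+nifD+nifK
KEY nifH+nifD+nifK

# ---- sulfur ----------------------------------------------------------

MODULE CUST_TAURINE sulfur Taurine import and dioxygenolysis
STEP tauA+tauC+tauB
STEP tauD
KEY tauD

MODULE CUST_DSR sulfur Dissimilatory sulfite reductase
STEP dsrA+dsrB
KEY dsrA+dsrB

MODULE CUST_SULFITE_OX sulfur Sulfite oxidation to sulfate
STEP sorA+sorB,SUOX,soeA+soeB+soeC
KEY sorA+sorB,SUOX,soeA+soeB+soeC

MODULE CUST_SOX sulfur Thiosulfate oxidation (SOX system)
STEP soxA+soxB+soxX+soxY+soxZ
KEY soxA+soxB+soxX+soxY+soxZ

MODULE M00176 sulfur Assimilatory sulfate reduction
STEP K00958,K00955+K00957,K00956+K00957
STEP K00860,K00955
STEP K00390
STEP K00380+K00381,K00392

# ---- phosphorus ------------------------------------------------------

MODULE CUST_AP phosphorus Alkaline phosphatase DOP hydrolysis
STEP phoA,phoB,phoD
KEY phoA,phoB,phoD

# ---- cobalamin -------------------------------------------------------

MODULE CUST_B12_AEROBIC cobalamin Aerobic cobalamin biosynthesis
STEP cobA
STEP cobI
STEP cobG
STEP cobJ
STEP cobM
STEP cobF
STEP cobK
STEP cobL
STEP cobH
STEP cobN+cobS+cobT
STEP cobO
STEP cobQ
STEP cobD
STEP cobP
STEP cobV
KEY cobN+cobS+cobT

MODULE CUST_B12_ANAEROBIC cobalamin Anaerobic cobalamin biosynthesis
STEP cbiK,cbiX
STEP cbiL
STEP cbiH
STEP cbiF
STEP cbiG
STEP cbiD
STEP cbiJ
STEP cbiE+cbiT
STEP cbiC
STEP cbiA
STEP cbiP
STEP cbiB
KEY cbiK,cbiX

MODULE CUST_B12_REMODEL cobalamin Pseudocobalamin remodelling to cobalamin
STEP cbiZ
STEP cbiB
KEY cbiZ
KEY cbiB

MODULE CUST_DMB cobalamin 5,6-dimethylbenzimidazole (DMB) synthesis
STEP bluB
KEY bluB

MODULE CUST_B12_TRANSPORT cobalamin TonB-dependent cobalamin transport
STEP btuB
KEY btuB

MODULE CUST_METH cobalamin B12-dependent methionine synthase
STEP metH
KEY metH

MODULE CUST_METE cobalamin B12-independent methionine synthase
STEP metE
KEY metE

# ---- auxin (IAA biosynthesis) ----------------------------------------

MODULE CUST_IAM auxin Indole-3-acetamide (IAM) pathway
STEP iaaM
STEP iaaH
KEY iaaM

MODULE CUST_IPYA auxin Indole-3-pyruvate (IPyA) pathway
STEP Tam1,IL4I1
STEP ipdC,YUCCA
STEP aldH
KEY ipdC

MODULE CUST_TAM auxin Tryptamine (TAM) pathway
STEP ddc
STEP maoA,tynA
STEP aldH
KEY ddc

MODULE CUST_IAN auxin Indole-3-acetonitrile (IAN) pathway
STEP CYP71A13,E3.2.1.147
STEP nthA+nthB,nit
KEY CYP71A13,E3.2.1.147

# ---- ethylene --------------------------------------------------------

MODULE CUST_ACC_DEAM ethylene ACC deaminase (ethylene precursor degradation)
STEP acdS
KEY acdS
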