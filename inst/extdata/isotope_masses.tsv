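symbol	mass
H	1.007825
He	4.002603
Li	7.016005
Be	9.012182
B	11.009305
C	12.000000
N	14.003074
O	15.994915
F	18.998403
Ne	19.992440
Na	22.989769
Mg	23.985042
Al	26.981539
Si	27.976927
P	30.973762
S	31.972071
Cl	34.968853
Ar	39.962383
K	38.963707
Ca	39.962591
Sc	44.955912
Ti	47.947946
V	50.943959
Cr	51.940508
Mn	54.938045
Fe	55.934937
Co	58.933195
Ni	57.935343
Cu	62.929597
Zn	63.929142
Ga	68.925574
Ge	73.921178
As	74.921597
Se	79.916521
Br	78.918337
Kr	83.911507
Rb	84.911790
Sr	87.905612
Y	88.905848
Zr	89.904704
Nb	92.906378
Mo	97.905408
Tc	96.906365
Ru	101.904349
Rh	102.905504
Pd	105.903486
Ag	106.905097
Cd	113.903358
In	114.903878
Sn	119.902195
Sb	120.903816
Te	129.906224
I	126.904473
Xe	131.904154
Cs	132.905452
Ba	137.905247
La	138.906353
Ce	139.905439
Pr	140.907653
Nd	141.907723
Pm	144.912749
Sm	151.919732
Eu	152.921230
Gd	157.924104
Tb	158.925347
Dy	163.929175
Ho	164.930322
Er	165.930293
Tm	168.934213
Yb	173.938862
Lu	174.940772
Hf	179.946550
Ta	180.947996
W	183.950931
Re	186.955753
Os	191.961481
Ir	192.962926
Pt	194.964791
Au	196.966569
Hg	201.970643
Tl	204.974427
Pb	207.976652
Bi	208.980399
Po	208.982430
At	209.987148
Rn	222.017571
Fr	223.019736
Ra	226.025403
Ac	227.027752
Th	232.038055
Pa	231.035884
U	238.050788
Np	236.046570
Pu	238.049560
Am	241.056829
Cm	243.061389
Bk	247.070307
Cf	249.074853
Es	252.082980
Fm	257.095105
Md	258.098431
No	259.101030
Lr	262.109630
Rf	267.121530
Db	268.125450
Sg	271.133470
Bh	270.133620
Hs	269.134060
Mt	278.154810
Ds	281.162060
Rg	281.165370
Cn	285.174110
Nh	284.178730
Fl	289.190420
Mc	288.192740
Lv	293.204490
Ts	292.207460
Og	294.213920
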