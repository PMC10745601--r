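# Standard periodic-table properties per column (stand-in scales; see package docs):
#   atomic_number: proton count
#   atomic_mass: standard atomic weight (u)
#   electronegativity: Pauling scale
#   covalent_radius: single-bond covalent radius (pm)
#   vdw_radius: van der Waals radius (pm)
#   valence_electrons: electrons in outer shell
#   period: periodic-table row
#   group: periodic-table column (main/transition group number)
#   ionization_energy: first ionization energy (eV)
symbol,atomic_number,atomic_mass,electronegativity,covalent_radius,vdw_radius,valence_electrons,period,group,ionization_energy
C,6,12.011,2.55,76,170,4,2,14,11.260
N,7,14.007,3.04,71,155,5,2,15,14.534
O,8,15.999,3.44,66,152,6,2,16,13.618
S,16,32.06,2.58,105,180,6,3,16,10.360
P,15,30.974,2.19,107,180,5,3,15,10.487
F,9,18.998,3.98,57,147,7,2,17,17.423
Cl,17,35.45,3.16,102,175,7,3,17,12.968
Br,35,79.904,2.96,120,185,7,4,17,11.814
I,53,126.904,2.66,139,198,7,5,17,10.451
B,5,10.81,2.04,84,192,3,2,13,8.298
Si,14,28.085,1.90,111,210,4,3,14,8.152
Se,34,78.971,2.55,120,190,6,4,16,9.752
As,33,74.922,2.18,119,185,5,4,15,9.789
H,1,1.008,2.20,31,120,1,1,1,13.598
Li,3,6.94,0.98,128,182,1,2,1,5.392
Na,11,22.990,0.93,166,227,1,3,1,5.139
K,19,39.098,0.82,203,275,1,4,1,4.341
Mg,12,24.305,1.31,141,173,2,3,2,7.646
Ca,20,40.078,1.00,176,231,2,4,2,6.113
Mn,25,54.938,1.55,139,197,7,4,7,7.434
Fe,26,55.845,1.83,132,194,8,4,8,7.902
Co,27,58.933,1.88,126,192,9,4,9,7.881
Ni,28,58.693,1.91,124,163,10,4,10,7.640
Cu,29,63.546,1.90,132,140,11,4,11,7.726
Zn,30,65.38,1.65,122,139,12,4,12,9.394
Sr,38,87.62,0.95,195,249,2,5,2,5.695
UNK,0,0,0,0,0,0,0,0,0
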