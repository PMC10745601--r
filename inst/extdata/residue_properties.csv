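# AAindex accession / description per column (stand-in scales; see package docs):
#   KYTJ820101: Hydropathy index (Kyte-Doolittle, 1982)
#   HOPT810101: Hydrophilicity value (Hopp-Woods, 1981)
#   EISD840101: Consensus normalized hydrophobicity scale (Eisenberg, 1984)
#   GRAR740102: Polarity (Grantham, 1974)
#   GRAR740103: Volume (Grantham, 1974)
#   ZIMJ680102: Bulkiness (Zimmerman et al., 1968)
#   ZIMJ680104: Isoelectric point (Zimmerman et al., 1968)
#   CHOC760101: Residue accessible surface area in tripeptide (Chothia, 1976)
#   FAUJ880103: Normalized van der Waals volume (Fauchere et al., 1988)
#   KLEP840101: Net charge (Klein et al., 1984)
#   FASG760101: Molecular weight (Fasman, 1976)
#   BHAR880101: Average flexibility indices (Bhaskaran-Ponnuswamy, 1988)
#   CHOP780201: Normalized frequency of alpha-helix (Chou-Fasman, 1978b)
#   CHOP780202: Normalized frequency of beta-sheet (Chou-Fasman, 1978b)
#   CHOP780203: Normalized frequency of beta-turn (Chou-Fasman, 1978b)
#   FAUJ880109: Number of hydrogen bond donors (Fauchere et al., 1988)
#   FAUJ880110: Number of full nonbonding orbitals (Fauchere et al., 1988)
#   FAUJ880111: Positive charge (Fauchere et al., 1988)
#   FAUJ880112: Negative charge (Fauchere et al., 1988)
#   DAWD720101: Size (Dawson, 1972)
#   JANJ780101: Average accessible surface area (Janin et al., 1978)
#   RADA880108: Mean polarity (Radzicka-Wolfenden, 1988)
#   CHAM820101: Polarizability parameter (Charton-Charton, 1982)
#   PONP800101: Surrounding hydrophobicity in folded form (Ponnuswamy et al., 1980)
symbol,KYTJ820101,HOPT810101,EISD840101,GRAR740102,GRAR740103,ZIMJ680102,ZIMJ680104,CHOC760101,FAUJ880103,KLEP840101,FASG760101,BHAR880101,CHOP780201,CHOP780202,CHOP780203,FAUJ880109,FAUJ880110,FAUJ880111,FAUJ880112,DAWD720101,JANJ780101,RADA880108,CHAM820101,PONP800101
A,1.8,-0.5,0.25,8.1,31,11.5,6,115,1,0,89.09,0.357,1.42,0.83,0.74,0,0,0,0,2.5,27.8,-0.06,0.046,12.28
C,2.5,-1,0.04,5.5,55,13.46,5.05,135,2.43,0,121.15,0.346,0.7,1.19,0.96,0,0,0,0,3,15.5,1.36,0.128,14.93
D,-3.5,3,-0.72,13,54,11.68,2.77,150,2.78,-1,133.1,0.511,1.01,0.54,1.52,1,4,0,1,2.5,60.6,-0.8,0.105,10.97
E,-3.5,3,-0.62,12.3,83,13.57,3.22,190,3.78,-1,147.13,0.497,1.51,0.37,0.95,1,4,0,1,5,68.2,-0.77,0.151,11.19
F,2.8,-2.5,0.61,5.2,132,19.8,5.48,210,5.89,0,165.19,0.314,1.13,1.38,0.66,0,0,0,0,6.5,25.5,1.27,0.29,13.43
G,-0.4,0,0.16,9,3,3.4,5.97,75,0,0,75.07,0.544,0.57,0.75,1.56,0,0,0,0,0.5,24.5,-0.41,0,12.01
H,-3.2,-0.5,-0.4,10.4,96,13.69,7.59,195,4.66,0,155.16,0.323,1,0.87,0.95,1,1,1,0,6,50.7,0.49,0.23,12.84
I,4.5,-1.8,0.73,5.2,111,21.4,6.02,175,4,0,131.17,0.462,1.08,1.6,0.47,0,0,0,0,5.5,22.8,1.31,0.186,14.77
K,-3.9,3,-1.1,11.3,119,15.71,9.74,200,4.77,1,146.19,0.466,1.16,0.74,1.19,2,1,1,0,7,103,-1.18,0.219,10.8
L,3.8,-1.8,0.53,4.9,111,21.4,5.98,170,4,0,131.17,0.365,1.21,1.3,0.5,0,0,0,0,5.5,27.6,1.21,0.186,14.1
M,1.9,-1.3,0.26,5.7,105,16.25,5.74,185,4.43,0,149.21,0.295,1.45,1.05,0.6,0,0,0,0,6,33.5,1.27,0.221,14.33
N,-3.5,0.2,-0.64,11.6,56,12.82,5.41,160,2.95,0,132.12,0.463,0.67,0.89,1.46,2,3,0,0,5,60.1,-0.48,0.134,11
P,-1.6,0,-0.07,8,32.5,17.43,6.3,145,2.72,0,115.13,0.509,0.57,0.55,1.56,0,0,0,0,5.5,51.5,0,0.131,11.19
Q,-3.5,0.2,-0.69,10.5,85,14.45,5.65,180,3.95,0,146.15,0.493,1.11,1.1,0.96,2,3,0,0,6,68.7,-0.73,0.18,11.28
R,-4.5,3,-1.76,10.5,124,14.28,10.76,225,6.13,1,174.2,0.529,0.98,0.93,1.01,4,3,1,0,7.5,94.7,-0.84,0.291,11.49
S,-0.8,0.3,-0.26,9.2,32,9.47,5.68,115,1.6,0,105.09,0.507,0.77,0.75,1.43,1,2,0,0,3,42,-0.5,0.062,11.26
T,-0.7,-0.4,-0.18,8.6,61,15.77,5.66,140,2.6,0,119.12,0.444,0.83,1.19,0.98,1,2,0,0,5,45,-0.27,0.108,11.65
V,4.2,-1.5,0.54,5.9,84,21.57,5.96,155,3,0,117.15,0.386,1.06,1.7,0.59,0,0,0,0,5,23.7,1.09,0.14,15.07
W,-0.9,-3.4,0.37,5.4,170,21.67,5.89,255,8.08,0,204.24,0.305,1.08,1.37,0.6,1,0,0,0,7,34.7,0.88,0.409,12.95
Y,-1.3,-2.3,0.02,6.2,136,18.03,5.66,230,6.47,0,181.19,0.42,0.69,1.47,1.14,1,2,0,0,7,55.2,0.33,0.298,13.29
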