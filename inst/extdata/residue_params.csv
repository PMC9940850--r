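# Default per-residue bead parameters for the one-bead-per-residue model.
# sigma_nm: bead Lennard-Jones size from a standard one-bead-per-residue
#   convention (amino-acid van der Waals diameters); a documented stand-in,
#   overridable by supplying another table with the same columns.
# charge: elementary units (Asp/Glu -1, Lys/Arg +1, His 0).
# mass_Da: average residue (monomer) mass.
code1,code3,sigma_nm,charge,mass_Da
A,ALA,0.504,0,71.08
R,ARG,0.656,1,156.19
N,ASN,0.568,0,114.10
D,ASP,0.558,-1,115.09
C,CYS,0.548,0,103.14
Q,GLN,0.602,0,128.13
E,GLU,0.592,-1,129.12
G,GLY,0.450,0,57.05
H,HIS,0.608,0,137.14
I,ILE,0.618,0,113.16
L,LEU,0.618,0,113.16
K,LYS,0.636,1,128.17
M,MET,0.618,0,131.19
F,PHE,0.636,0,147.18
P,PRO,0.556,0,97.12
S,SER,0.518,0,87.08
T,THR,0.562,0,101.10
W,TRP,0.678,0,186.21
Y,TYR,0.646,0,163.18
V,VAL,0.586,0,99.13
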