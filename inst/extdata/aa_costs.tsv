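name	cost	source
A	11.7	ecoli_aerobic_respiration
R	27.3	ecoli_aerobic_respiration
N	14.7	ecoli_aerobic_respiration
D	12.7	ecoli_aerobic_respiration
C	24.7	ecoli_aerobic_respiration
Q	16.3	ecoli_aerobic_respiration
E	15.3	ecoli_aerobic_respiration
G	11.7	ecoli_aerobic_respiration
H	38.3	ecoli_aerobic_respiration
I	32.3	ecoli_aerobic_respiration
L	27.3	ecoli_aerobic_respiration
K	30.3	ecoli_aerobic_respiration
M	34.3	ecoli_aerobic_respiration
F	52.0	ecoli_aerobic_respiration
P	20.3	ecoli_aerobic_respiration
S	11.7	ecoli_aerobic_respiration
T	18.7	ecoli_aerobic_respiration
W	74.3	ecoli_aerobic_respiration
Y	50.0	ecoli_aerobic_respiration
V	23.3	ecoli_aerobic_respiration
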