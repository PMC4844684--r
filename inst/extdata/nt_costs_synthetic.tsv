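name	cost	source
A	46.9	synthetic_ordering_compliant
C	43.4	synthetic_ordering_compliant
G	49.3	synthetic_ordering_compliant
U	42.3	synthetic_ordering_compliant
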