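# Published H-strand base counts of the H. quoyi mitogenome (whole genome).
base	count
A	4838
T	4550
G	2534
C	4603
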