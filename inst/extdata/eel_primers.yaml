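# Benchmark primer pair: a published eel (Anguilla) eDNA metabarcoding pair
# targeting a 167 bp variable core of the mitochondrial ATP6 gene.
primers:
  - name: MiEel
    forward: CTTACAGCAAACCTGACAGCAG
    reverse: TTGGTGTGCCATTATACGTTTTCTTG
    max_core_len: 200
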