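# Example CDE-style sRBNS design: two stem-loop scaffolds with a randomized
# tri/tetra/penta-nucleotide loop. The arm sequences are SYNTHETIC stand-ins
# (the published UCP3/TNF stems are not reproduced here); they honour the
# documented closing-pair orientations: purine-pyrimidine (A-U) for the
# UCP3-like scaffold and pyrimidine-purine (C-G) for the TNF-like scaffold,
# each with a 6 bp Watson-Crick stem.
loop_lengths: [3, 4, 5]
scaffolds:
  - name: UCP3
    arm5: AAGCGUCCGA
    arm3: UCGGACCUUC
  - name: TNF
    arm5: CUGUAGGCUC
    arm3: GAGCCUAGUU
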