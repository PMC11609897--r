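# Example ADE-style sRBNS design: two stem-loop scaffolds capped with all
# 4096 hexanucleotide loops. Arm sequences are SYNTHETIC stand-ins for the
# HOMEZ/ITCH ADE stems (6 bp Watson-Crick stems).
loop_lengths: [6]
scaffolds:
  - name: HOMEZ
    arm5: AUCAGGUGCC
    arm3: GGCACCAAUC
  - name: ITCH
    arm5: GAAUUGCUGG
    arm3: CCAGCAUUCG
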