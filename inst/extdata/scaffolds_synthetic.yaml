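# Synthetic example scaffold templates.
#
# The sdAb entry is a synthetic VHH-like framework composed for testing,
# with the conserved framework cysteines placed at raw indices 23 and 97
# and a 12-residue CDR3 site. The monobody entry is the wild-type tenth
# fibronectin type-III domain (10FN3) with its BC and FG binding loops.
# Neither is claimed to be identical to any published designed-antibody
# scaffold; supply your own template file for exact sequences.
scaffolds:
  sdAb:
    sequence: QVQLVESGGGLVQPGGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSAINSGGGSTYYADSVKGRFTISRDNAKNTLYLQMNSLKPEDTAVYYCAKAADSTIYASYYEWGQGTQVTVSS
    sites:
      CDR3: [100, 111]
    numbered:
      C23: 23
      C97: 97
    numbering_offset: 0
    n_terminal_region: 22
  monobody:
    sequence: VSDVPRDLEVVAATPTSLLISWDAPAVTVRYYRITYGETGGNSPVQEFTVPGSKSTATISGLKPGVDYTITVYAVTGRGDSPASSKPISINYRT
    sites:
      BC: [23, 30]
      FG: [77, 86]
    numbering_offset: 0
    n_terminal_region: 8
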