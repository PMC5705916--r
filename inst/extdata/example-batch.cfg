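# Standard 300-h batch coculture at a producer-biased NH4+ affinity.
# Keys: scenario settings, parameter fields (Table-style names), init.* states.
scenario: batch
variant: default
duration: 300
affinity_ratio: 10
R_A: 0.15          # fmol NH4+ excreted per new R. palustris cell
init.G: 25         # mM glucose in fresh medium
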