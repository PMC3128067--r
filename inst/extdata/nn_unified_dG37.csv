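# Unified Watson-Crick nearest-neighbour free energies, dG37 in kcal/mol
# (SantaLucia 1998 unified parameter set). "stack" is the 5'->3' dinucleotide
# on the probe strand; complementary stacks share the same value.
# Initiation terms are per duplex terminus, by terminal base pair class.
type,stack,dG37
stack,AA,-1.00
stack,AT,-0.88
stack,TA,-0.58
stack,CA,-1.45
stack,GT,-1.44
stack,CT,-1.28
stack,GA,-1.30
stack,CG,-2.17
stack,GC,-2.24
stack,GG,-1.84
init,AT_terminus,1.03
init,GC_terminus,0.98
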