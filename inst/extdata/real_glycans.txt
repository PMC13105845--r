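# 22 well-known glycan structures in IUPAC-condensed notation
# (N-glycans, O-glycan cores, milk oligosaccharides, ganglioside cores,
#  a plant xylosylated core, a GAG linker); one per line, optional tab+class
Man(a1-3)[Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Man(a1-2)Man(a1-6)[Man(a1-2)Man(a1-3)]Man(a1-6)[Man(a1-2)Man(a1-2)Man(a1-3)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Man(a1-3)[Man(a1-6)]Man(a1-6)[Man(a1-3)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc	N
NeuNAc(a2-6)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[NeuNAc(a2-6)Gal(b1-4)GlcNAc(b1-2)Man(a1-6)]Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Xyl(b1-2)Man(b1-4)GlcNAc(b1-4)GlcNAc	N
Gal(b1-3)GalNAc	O
Gal(b1-3)[GlcNAc(b1-6)]GalNAc	O
GlcNAc(b1-3)GalNAc	O
GlcNAc(b1-6)GalNAc	O
NeuNAc(a2-3)Gal(b1-3)GalNAc	O
NeuNAc(a2-3)Gal(b1-3)[NeuNAc(a2-6)]GalNAc	O
Fuc(a1-2)Gal(b1-4)Glc	free
Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc	free
Gal(b1-4)GlcNAc(b1-3)Gal(b1-4)Glc	free
Gal(b1-4)[Fuc(a1-3)]GlcNAc(b1-3)Gal(b1-4)Glc	free
Fuc(a1-2)Gal(b1-3)GlcNAc(b1-3)Gal(b1-4)Glc	free
NeuNAc(a2-3)Gal(b1-4)Glc	free
NeuNAc(a2-6)Gal(b1-4)Glc	free
GalNAc(b1-4)[NeuNAc(a2-3)]Gal(b1-4)Glc	free
Gal(b1-3)GalNAc(b1-4)[NeuNAc(a2-3)]Gal(b1-4)Glc	free
GlcA(b1-3)Gal(b1-3)Gal(b1-4)Xyl	free
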