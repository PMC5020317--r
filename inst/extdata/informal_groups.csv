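informalGroup,higherGroup
terrestrial mammal,mammals
bird,birds
beetle,invertebrates
dragonfly,invertebrates
butterfly,invertebrates
moth,invertebrates
true bug,invertebrates
spider,invertebrates
fungus,fungi & lichens
flowering plant,plants
other,others
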