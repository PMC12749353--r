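format-version: 1.2
ontology: mini-go

[Term]
id: GO:0005575
name: cellular_component
namespace: cellular_component

[Term]
id: GO:0043226
name: organelle
namespace: cellular_component
is_a: GO:0005575 ! cellular_component

[Term]
id: GO:0005739
name: mitochondrion
namespace: cellular_component
is_a: GO:0043226 ! organelle

[Term]
id: GO:0016020
name: membrane
namespace: cellular_component
is_a: GO:0005575 ! cellular_component

[Term]
id: GO:0031966
name: mitochondrial membrane
namespace: cellular_component
is_a: GO:0016020 ! membrane
relationship: part_of GO:0005739 ! mitochondrion

[Term]
id: GO:0005743
name: mitochondrial inner membrane
namespace: cellular_component
is_a: GO:0016020 ! membrane
relationship: part_of GO:0031966 ! mitochondrial membrane

[Term]
id: GO:0005737
name: cytoplasm
namespace: cellular_component
is_a: GO:0005575 ! cellular_component

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:0003824
name: catalytic activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0000001
name: obsolete test term
namespace: cellular_component
is_obsolete: true
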