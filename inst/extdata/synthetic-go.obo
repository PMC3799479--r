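format-version: 1.2
ontology: synthetic-demo

[Term]
id: GO:0000001
name: molecular activity (synthetic root)
namespace: demo_function

[Term]
id: GO:0000002
name: binding (synthetic)
namespace: demo_function
is_a: GO:0000001 ! molecular activity

[Term]
id: GO:0000003
name: catalysis (synthetic)
namespace: demo_function
is_a: GO:0000001 ! molecular activity

[Term]
id: GO:0000004
name: protein binding (synthetic)
namespace: demo_function
is_a: GO:0000002 ! binding

[Term]
id: GO:0000005
name: catalytic binding (synthetic)
namespace: demo_function
is_a: GO:0000002 ! binding
is_a: GO:0000003 ! catalysis

[Term]
id: GO:0000006
name: hydrolase activity (synthetic)
namespace: demo_function
is_a: GO:0000003 ! catalysis
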