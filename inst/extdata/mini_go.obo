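format-version: 1.2
ontology: mini-go-synthetic
remark: small synthetic ontology fixture for tests and the demo pipeline

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:1000001
name: cell adhesion
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:1000002
name: signal transduction
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:1000003
name: mucosal defense response
namespace: biological_process
is_a: GO:1000001 ! cell adhesion
is_a: GO:1000002 ! signal transduction

[Term]
id: GO:1000004
name: epithelial maintenance
namespace: biological_process
is_a: GO:1000001 ! cell adhesion

[Term]
id: GO:2000001
name: protein binding
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:2000002
name: extracellular matrix structural constituent
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:2000003
name: glycoprotein binding
namespace: molecular_function
is_a: GO:2000001 ! protein binding

[Term]
id: GO:2000004
name: obsolete placeholder activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function
is_obsolete: true
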