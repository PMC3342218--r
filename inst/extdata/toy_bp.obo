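format-version: 1.2
ontology: synthetic toy ontology for parser tests

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process

[Term]
id: GO:0009987
name: cellular process
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0016043
name: cellular component organization
namespace: biological_process
is_a: GO:0009987 ! cellular process

[Term]
id: GO:0006996
name: organelle organization
namespace: biological_process
is_a: GO:0016043 ! cellular component organization
is_a: GO:0009987 ! cellular process

[Term]
id: GO:0051179
name: localization
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:0005215
name: transporter activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0000001
name: obsolete example term
namespace: biological_process
is_obsolete: true
is_a: GO:0008150 ! biological_process
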