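suture,region,origin
interfrontal,vault,neural_crest
fronto-parietal,vault,boundary
interparietal,vault,mesoderm
supraoccipito-parietal,vault,mesoderm
basispheno-presphenoid,cranial base,boundary
basispheno-basioccipital,cranial base,mesoderm
exoccipito-basioccipital,cranial base,mesoderm
exoccipito-squamosal,cranial base,boundary
exoccipito-supraoccipital,cranial base,mesoderm
alispheno-squamosal,circum-meatal,neural_crest
alispheno-orbitosphenoid,circum-meatal,neural_crest
orbitospheno-frontal,circum-meatal,neural_crest
fronto-squamosal,circum-meatal,neural_crest
parieto-squamosal,circum-meatal,boundary
supraoccipito-squamosal,circum-meatal,boundary
interpremaxillary,palate,neural_crest
intermaxillary,palate,neural_crest
premaxillo-maxillary-ventral,palate,neural_crest
interpalatine,palate,neural_crest
maxillo-palatine,palate,neural_crest
pterygo-palatine,palate,neural_crest
premaxillo-maxillary-facial,facial,neural_crest
premaxillo-nasal,facial,neural_crest
internasal,facial,neural_crest
maxillo-jugal,facial,neural_crest
maxillo-lacrimal,facial,neural_crest
naso-frontal,cranio-facial,neural_crest
lacrimo-frontal,cranio-facial,neural_crest
jugo-squamosal,cranio-facial,neural_crest
palato-alisphenoid,cranio-facial,neural_crest
palato-orbitosphenoid,cranio-facial,neural_crest
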