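dataset,region,closure_pct
full,vault,86.36
full,cranial base,72.27
full,circum-meatal,77.08
full,palate,72.54
full,facial,73.41
full,cranio-facial,75.68
placental,vault,87.92
placental,cranial base,76.33
placental,circum-meatal,79.17
placental,palate,73.33
placental,facial,72.67
placental,cranio-facial,72.67
marsupial,vault,83.04
marsupial,cranial base,63.57
marsupial,circum-meatal,72.62
marsupial,palate,70.83
marsupial,facial,75.00
marsupial,cranio-facial,82.14
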