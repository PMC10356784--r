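ENTRY       R00299                      Reaction
NAME        ATP:D-glucose 6-phosphotransferase
EQUATION    C00002 + C00031 <=> C00008 + C00092
ENZYME      2.7.1.1         2.7.1.2
///
ENTRY       R00771                      Reaction
NAME        D-glucose-6-phosphate aldose-ketose-isomerase
EQUATION    C00092 <=> C00085
ENZYME      5.3.1.9
///
ENTRY       R00756                      Reaction
NAME        ATP:D-fructose-6-phosphate 1-phosphotransferase
EQUATION    C00002 + C00085 <=> C00008 + C00354
ENZYME      2.7.1.11
///
ENTRY       R01068                      Reaction
NAME        D-fructose-1,6-bisphosphate D-glyceraldehyde-3-phosphate-lyase
EQUATION    C00354 <=> C00111 + C00118
ENZYME      4.1.2.13
///
ENTRY       R01015                      Reaction
NAME        D-glyceraldehyde-3-phosphate aldose-ketose-isomerase
EQUATION    C00118 <=> C00111
ENZYME      5.3.1.1
///
ENTRY       R00959                      Reaction
NAME        alpha-D-glucose 1,6-phosphomutase
EQUATION    C00103 <=> C00092
ENZYME      5.4.2.2
///
ENTRY       R02740                      Reaction
NAME        beta-D-glucose 6-phosphate ketol-isomerase (plant-only fixture)
EQUATION    C01172 <=> C00085
ENZYME      5.3.1.99
///
ENTRY       R09999                      Reaction
NAME        malformed record kept for parser robustness
EQUATION    C00031 + <=> C00092
ENZYME      2.7.1.1
///
ENTRY       R05605                      Reaction
NAME        catalase-like water-splitting toy record
EQUATION    2 C00027 <=> 2 C00001 + C00007
ENZYME      1.11.1.6
///
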