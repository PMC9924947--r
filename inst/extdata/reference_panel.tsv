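strain	lifespan_extension_pct	heat	oxidative_chronic	oxidative_acute	pathogen	osmotic	anoxia
ife-2	26.3	increased	decreased	decreased	increased	decreased	unchanged
clk-1	33.4	increased	increased	decreased	increased	unchanged	unchanged
sod-2	37.2	increased	decreased	decreased	increased	unchanged	unchanged
eat-2	45.6	increased	increased	increased	decreased	decreased	unchanged
osm-5	65.4	increased	increased	increased	increased	increased	increased
nuo-6	79.2	increased	increased	unchanged	increased	increased	decreased
isp-1	83.8	increased	increased	increased	increased	increased	unchanged
glp-1	89.2	increased	increased	decreased	increased	increased	increased
daf-2	138.4	increased	increased	increased	increased	increased	increased
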