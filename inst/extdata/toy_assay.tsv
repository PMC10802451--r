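culture	genotype	treatment	canr_per_ml	viable_per_ml
c01	rad1	water	10	10000000
c02	rad1	water	20	10000000
c03	rad1	water	20	10000000
c04	rad1	water	30	10000000
c05	rad1	water	30	10000000
c06	rad1	water	40	10000000
c07	rad1	acetaldehyde	40	10000000
c08	rad1	acetaldehyde	50	10000000
c09	rad1	acetaldehyde	60	10000000
c10	rad1	acetaldehyde	60	10000000
c11	rad1	acetaldehyde	70	10000000
c12	rad1	acetaldehyde	80	10000000
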