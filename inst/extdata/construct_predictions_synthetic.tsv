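construct_id	predicted_tissues
c01	brain,neural_tube
c02	brain,neural_tube
c03	brain,neural_tube
c04	brain,neural_tube
c05	brain,heart
c06	brain,heart
c07	brain,heart
c08	brain,heart
c09	brain,other
c10	brain,other
c11	brain,other
c12	brain
c13	brain
c14	limb
c15	limb
c16	limb
c17	limb
c18	limb
c19	limb
c20	limb
c21	limb
c22	neural_tube
c23	neural_tube
c24	neural_tube
c25	other
c26	other
c27	other
c28	other
c29	other
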