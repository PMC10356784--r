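ec:2.7.1.1	hsa:3098
ec:2.7.1.2	hsa:2645
ec:5.3.1.9	hsa:2821
ec:2.7.1.11	hsa:5213
ec:4.1.2.13	hsa:226
ec:5.3.1.1	hsa:7167
ec:5.4.2.2	hsa:5236
ec:1.11.1.6	hsa:847
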