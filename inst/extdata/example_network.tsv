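# worked-example network: 11 nodes, 16 edges
v1	v2
v1	v3
v1	v8
v1	v9
v2	v3
v2	v7
v3	v4
v4	v5
v4	v6
v4	v7
v6	v7
v8	v9
v8	v11
v9	v10
v9	v11
v10	v11
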