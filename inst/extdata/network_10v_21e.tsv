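v1	v8
v1	v9
v1	v10
v2	v3
v2	v7
v2	v8
v2	v9
v2	v10
v3	v7
v4	v5
v4	v8
v4	v9
v5	v6
v5	v8
v5	v10
v6	v9
v6	v10
v7	v9
v8	v9
v8	v10
v9	v10
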