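v1	v5
v1	v7
v1	v9
v1	v11
v1	v16
v2	v14
v2	v19
v3	v12
v3	v13
v3	v16
v3	v19
v4	v7
v4	v14
v4	v18
v5	v6
v5	v10
v5	v13
v5	v14
v5	v16
v5	v18
v5	v20
v6	v11
v6	v12
v6	v13
v6	v18
v7	v8
v7	v18
v7	v20
v8	v13
v8	v15
v9	v14
v9	v16
v9	v17
v10	v14
v10	v19
v11	v19
v12	v19
v14	v15
v14	v20
v15	v17
v16	v18
v16	v19
v16	v20
v17	v19
v18	v20
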