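v1 v2
v2 v3
v3 v4
v1 v4
v1 v3
v6 v7
v7 v8
v6 v8
v9 v10
v9 v11
v9 v12
v1 v5
v6 v5
v9 v5
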