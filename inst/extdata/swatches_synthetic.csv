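R,G,B
115,82,68
194,150,130
98,122,157
87,108,67
133,128,177
103,189,170
214,126,44
80,91,166
193,90,99
94,60,108
157,188,64
224,163,46
56,61,150
70,148,73
175,54,60
231,199,31
187,86,149
62,133,161
129,196,231
243,243,242
200,200,200
160,160,160
122,122,121
85,85,85
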