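time,speed_in,speed_out
62.429252064143,0.442027863013,0.353622290411
63.193461196813,0.339184843681,0.271347874945
64.080969324084,0.155003933170,0.124003146536
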