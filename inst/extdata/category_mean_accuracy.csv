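category,CR,LG,OED,UCSB
handcrafted,84.48,90.42,87.03,72.41
deep,99.27,98.49,96.28,91.38
xai,83.82,86.98,80.88,78.28
ens_handcrafted_deep,99.76,99.02,96.49,90.52
ens_deep,100,99.66,97.23,92.93
ens_xai,86.18,89.62,78.85,78.45
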