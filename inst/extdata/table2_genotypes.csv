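isolate_id,genotype_string,batch
R1,csm2(ΔA297). Frameshift,R
R2,"Δspc1,2,3",R
R3,csm6(617)::IS256-d,R
R4,csm6(617)::IS256-d,R
R11,csm6(617)::IS256-d,R
R13,csm6(617)::IS256-d,R
R5,cas10(ΔA979). Frameshift,R
R8,cas10(ΔA979). Frameshift,R
R18,cas10(ΔA979). Frameshift,R
R30,cas10(ΔA979). Frameshift,R
R42,cas10(ΔA979). Frameshift,R
R6,csm4(ΔA57). Frameshift,R
R7,Δ2387081–2520252 (IS256),R
R24,Δ2387081–2520252 (IS256),R
R32,Δ2387081–2520252 (IS256),R
R50,Δ2387081–2520252 (IS256),R
R56,Δ2387081–2520252 (IS256),R
R65,Δ2387081–2520252 (IS256),R
R70,Δ2387081–2520252 (IS256),R
R9,Δ2470979–2553341 (SERP2409&SERP2493),R
R12,Δ2470979–2553341 (SERP2409&SERP2493),R
R25,Δ2470979–2553341 (SERP2409&SERP2493),R
R27,Δ2470979–2553341 (SERP2409&SERP2493),R
R39,Δ2470979–2553341 (SERP2409&SERP2493),R
R41,Δ2470979–2553341 (SERP2409&SERP2493),R
R45,Δ2470979–2553341 (SERP2409&SERP2493),R
R59,Δ2470979–2553341 (SERP2409&SERP2493),R
R10,"Δspc1,2",R
R19,"Δspc1,2",R
R28,"Δspc1,2",R
R34,"Δspc1,2",R
R47,"Δspc1,2",R
R58,"Δspc1,2",R
R63,"Δspc1,2",R
B32,"Δspc1,2",B
R14,Δ2515497–2581208 (IS431),R
R15,Δ2488334–2581208 (IS431),R
R16,Δ2399891–2551562 (SERP2353&SERP2491),R
R33,Δ2399891–2551562 (SERP2353&SERP2491),R
R37,Δ2399891–2551562 (SERP2353&SERP2491),R
R40,Δ2399891–2551562 (SERP2353&SERP2491),R
R49,Δ2399891–2551562 (SERP2353&SERP2491),R
R54,Δ2399891–2551562 (SERP2353&SERP2491),R
R55,Δ2399891–2551562 (SERP2353&SERP2491),R
R57,Δ2399891–2551562 (SERP2353&SERP2491),R
R61,Δ2399891–2551562 (SERP2353&SERP2491),R
R62,Δ2399891–2551562 (SERP2353&SERP2491),R
R67,Δ2399891–2551562 (SERP2353&SERP2491),R
B3,Δ2399891–2551562 (SERP2353&SERP2491),B
B6,Δ2399891–2551562 (SERP2353&SERP2491),B
B9,Δ2399891–2551562 (SERP2353&SERP2491),B
B18,Δ2399891–2551562 (SERP2353&SERP2491),B
R17,cas6(193)::IS256-d,R
R20,spc1(ΔA1),R
R22,Δ2493652–2584194 (OrfX),R
R23,Δspc1,R
R31,Δspc1,R
R46,Δspc1,R
B7,Δspc1,B
B19,Δspc1,B
R29,Δ2496588–2581208 (IS431),R
R35,Δ2295499–2535027 (IS256),R
R36,cas6(199)::IS256-d,R
R48,cas6(199)::IS256-d,R
R38,csm6(1059)::IS256-d,R
R44,csm6(1059)::IS256-d,R
R68,csm6(1059)::IS256-d,R
R43,csm4(G566T; G189V),R
R51,Δ2515497–2581208 (IS431),R
R52,cas10(C1411T; Q471Stop),R
R53,csm2(ΔA297). Frameshift,R
R69,csm2(ΔA297). Frameshift,R
B8,csm2(ΔA297). Frameshift,B
B12,csm2(ΔA297). Frameshift,B
R60,csm5(558)::IS256-i,R
R64,csm5(558)::IS256-i,R
R66,cas10(G1017A; W339Stop),R
R71,cas6(269)::IS256-d,R
B1,Δ2433266–2581208 (IS431),B
B2,Δ2437916–2581208 (IS431),B
B10,Δ2437916–2581208 (IS431),B
B11,Δ2437916–2581208 (IS431),B
B21,Δ2437916–2581208 (IS431),B
B25,Δ2437916–2581208 (IS431),B
B27,Δ2437916–2581208 (IS431),B
B31,Δ2437916–2581208 (IS431),B
B40,Δ2437916–2581208 (IS431),B
B42,Δ2437916–2581208 (IS431),B
B4,Δ2440320–2582329 (IS256),B
B5,Δ2440320–2582329 (IS256),B
B29,Δ2440320–2582329 (IS256),B
B38,Δ2440320–2582329 (IS256),B
B13,csm6(1172)::IS256-i,B
B14,csm6(1172)::IS256-i,B
B22,csm6(1172)::IS256-i,B
B15,csm6(953)::IS256-d,B
B16,csm6(953)::IS256-d,B
B33,csm6(953)::IS256-d,B
B17,Δ2359213–2581208 (IS431),B
B20,csm6(ΔA1238). Frameshift,B
B23,Δ2401725–2562431 (Tn554),B
B24,csm6(844)::IS256-i,B
B26,cas6(ΔA172). Frameshift,B
B28,Δ2447777–2581208 (IS431),B
B30,Δ2495387–2581208 (IS431),B
B34,csm5(583)::IS256-i,B
B35,csm5(583)::IS256-i,B
B36,csm5(583)::IS256-i,B
B37,cas6(G484T; E162Stop),B
B39,Δ2274721–2581208 (IS256),B
B41,csm6(1163)::IS256-i,B
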