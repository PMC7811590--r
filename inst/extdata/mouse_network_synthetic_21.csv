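"id","parent_id","length_cm","r0_cm","terminal"
1,,0.423,0.047,FALSE
2,1,0.337099720187696,0.0374555244652996,FALSE
3,1,0.356620279812304,0.0396244755347004,FALSE
4,3,0.287941273513914,0.0319934748348794,FALSE
5,3,0.296915985378264,0.0329906650420293,FALSE
6,2,0.278838361236536,0.0309820401373928,FALSE
7,2,0.274005179871286,0.0304450199856985,FALSE
8,5,0.255397524361586,0.0283775027068429,FALSE
9,5,0.231544691658767,0.0257271879620852,TRUE
10,4,0.227659472747984,0.0252954969719982,TRUE
11,4,0.244564215814835,0.0271738017572039,FALSE
12,6,0.239578350779928,0.0266198167533254,FALSE
13,6,0.21771656164799,0.0241907290719989,TRUE
14,7,0.236673630867173,0.0262970700963526,TRUE
15,7,0.212694864121736,0.0236327626801929,TRUE
16,8,0.213466998015897,0.0237185553350997,TRUE
17,8,0.205384941937104,0.0228205491041227,TRUE
18,11,0.203649801778011,0.0226277557531124,TRUE
19,11,0.197435512158319,0.0219372791287021,TRUE
20,12,0.186123573814668,0.0206803970905187,TRUE
21,12,0.206784921464415,0.022976102384935,TRUE
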