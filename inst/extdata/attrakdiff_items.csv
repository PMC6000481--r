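item,subscale,anchor_low,anchor_high,polarity
1,pragmatic_quality,technical,human,1
2,pragmatic_quality,complicated,simple,1
3,pragmatic_quality,impractical,practical,1
4,pragmatic_quality,cumbersome,straightforward,1
5,pragmatic_quality,unpredictable,predictable,1
6,pragmatic_quality,confusing,clearly structured,1
7,pragmatic_quality,unruly,manageable,1
8,hedonic_identity,isolating,connective,1
9,hedonic_identity,unprofessional,professional,1
10,hedonic_identity,tasteless,stylish,1
11,hedonic_identity,cheap,premium,1
12,hedonic_identity,alienating,integrating,1
13,hedonic_identity,separates me,brings me closer,1
14,hedonic_identity,unpresentable,presentable,1
15,hedonic_stimulation,conventional,inventive,1
16,hedonic_stimulation,unimaginative,creative,1
17,hedonic_stimulation,cautious,bold,1
18,hedonic_stimulation,conservative,innovative,1
19,hedonic_stimulation,dull,captivating,1
20,hedonic_stimulation,undemanding,challenging,1
21,hedonic_stimulation,ordinary,novel,1
22,attractiveness,unpleasant,pleasant,1
23,attractiveness,ugly,attractive,1
24,attractiveness,disagreeable,likeable,1
25,attractiveness,rejecting,inviting,1
26,attractiveness,bad,good,1
27,attractiveness,repelling,appealing,1
28,attractiveness,discouraging,motivating,1
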