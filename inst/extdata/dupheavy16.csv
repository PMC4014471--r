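0.78069204487837851,0.070232489379122853,0.20227068872191012,0.78069204487837851,0.23532161698676646,0.78957889205776155,0.78069204487837851,0.23532161698676646,0.070232489379122853,0.20227068872191012,0.59243181976489723,0.2987066360656172,0.070232489379122853,0.95212487527169287,0.23532161698676646,0.20227068872191012
0.33696452528238297,0.63907806389033794,0.96678585535846651,0.33696452528238297,0.75431884918361902,0.59663026174530387,0.33696452528238297,0.75431884918361902,0.63907806389033794,0.96678585535846651,0.60570055176503956,0.033090354641899467,0.63907806389033794,0.78455680515617132,0.75431884918361902,0.96678585535846651
0.53206409350968897,0.39263739273883402,0.061395637923851609,0.53206409350968897,0.42444903426803648,0.35667053377255797,0.53206409350968897,0.42444903426803648,0.39263739273883402,0.061395637923851609,0.7235226018819958,0.038802352966740727,0.39263739273883402,0.91411868203431368,0.42444903426803648,0.061395637923851609
0.027522589778527617,0.80031853634864092,0.41792390681803226,0.027522589778527617,0.42566847964189947,0.75870834174565971,0.027522589778527617,0.42566847964189947,0.80031853634864092,0.41792390681803226,0.69265333632938564,0.19423621660098433,0.80031853634864092,0.41177238989621401,0.42566847964189947,0.41792390681803226
0.25058753532357514,0.61151305260136724,0.17302190419286489,0.25058753532357514,0.90909936302341521,0.26105076563544571,0.25058753532357514,0.90909936302341521,0.61151305260136724,0.17302190419286489,0.97731280047446489,0.04654577374458313,0.61151305260136724,0.43540381942875683,0.90909936302341521,0.17302190419286489
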