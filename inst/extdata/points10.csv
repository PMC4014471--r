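0.24745585746131837,0.32902580522932112,0.52916481113061309,0.42559507093392313,0.41252409131266177,0.13473496772348881,0.75131201231852174,0.19216701597906649,0.4262017160654068,0.2704739982727915
0.21501122880727053,0.86388782598078251,0.83436303935013711,0.31220464874058962,0.81570256012491882,0.75236334325745702,0.18279754789546132,0.61973514081910253,0.20451182825490832,0.33234451478347182
0.49367376230657101,0.6377899032086134,0.50285592349246144,0.22192722489126027,0.16265891678631306,0.17408360657282174,0.057340506464242935,0.68604727741330862,0.93889392865821719,0.36401154077611864
0.65344602684490383,0.013780595501884818,0.59776076558046043,0.4434262290596962,0.59698338946327567,0.57983313547447324,0.49848769116215408,0.42554839653894305,0.53572897473350167,0.22029982856474817
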