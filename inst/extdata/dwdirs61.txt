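0.14156539 -0.02617856 0.9895827
-0.12787316 0.15715798 0.97925984
-0.18702274 -0.17826787 0.96604506
0.10811064 -0.34540434 0.93220595
0.16100595 0.33116767 0.92973386
0.42188212 0.11388681 0.89946944
-0.46042696 0.00958049 0.88764589
0.42275539 -0.2262637 0.87754351
-0.38174737 0.32253572 0.86616376
-0.11857653 0.50997241 0.85197872
-0.2244431 -0.49298171 0.84059165
-0.4909885 -0.3068871 0.81532239
0.06356581 -0.62582296 0.77737057
0.43117874 0.46670123 0.77218835
0.37451109 -0.54012564 0.75366155
0.1592486 0.64491368 0.74747992
0.68828255 -0.08083457 0.72092503
0.65566737 0.24088092 0.71559533
-0.65665901 0.2711855 0.70374524
-0.72536457 -0.06217931 0.68555085
-0.44538487 0.58044426 0.68170138
0.64828809 -0.3965598 0.64997144
-0.46361553 -0.61961007 0.6333593
-0.16224417 0.76210372 0.62679721
-0.16357163 -0.77891193 0.60542591
-0.7097947 -0.38831998 0.58770662
0.20660346 -0.80804802 0.55170047
0.44753403 0.71410878 0.53829541
0.70332471 0.49003028 0.51498026
0.13974681 0.85521938 0.49906978
0.52302844 -0.69726823 0.49016146
0.86222395 0.1516348 0.48329779
-0.71005069 0.51900081 0.47588463
-0.86424322 0.1907143 0.46552305
0.87105578 -0.18783313 0.4538508
-0.46237681 0.77895851 0.42359334
-0.9060266 -0.12671494 0.40380579
0.7786857 -0.50547747 0.37167339
-0.37520441 -0.85075805 0.36801141
-0.64892333 -0.67425022 0.35254098
-0.02477848 -0.94037076 0.33924749
-0.18706145 0.92569091 0.32879226
-0.85231578 -0.42832134 0.30016435
0.32890971 -0.90617789 0.26581955
0.6768999 0.68928779 0.25824186
0.88636972 0.39334815 0.24418425
0.4118928 0.87854835 0.24186175
-0.89222013 0.39725784 0.21477769
0.10572161 0.97403275 0.20020777
0.97914412 0.04562242 0.19797825
-0.68094615 0.70651679 0.19273395
0.61077827 -0.77340004 0.16971235
-0.98664246 0.07765795 0.14319881
0.952627 -0.27300818 0.13404599
-0.25328161 -0.96343823 0.08737964
-0.42352313 0.90194074 0.08444562
-0.56312088 -0.82428335 0.05875238
0.82626229 -0.56044068 0.05654084
-0.96643349 -0.25096469 0.05498215
0.11689346 -0.99257409 0.03365413
-0.80753432 -0.58936021 0.02329952
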