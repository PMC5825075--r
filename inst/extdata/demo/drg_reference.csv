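"drg","avg_overnight_los","cost_weight","ward nursing","ward medical","non-clinical salaries","pathology","imaging","allied health","pharmacy","supplies","on-costs","hotel","depreciation","critical care","operating rooms","emergency departments","special procedure suites","prosthesis"
"D001",5.04,0.3739,382.98,78.43,88.4,365.02,19.74,483.25,8.66,1114.32,16.16,243.12,44.32,185.26,149.53,133.86,44.08,85.52
"D002",2.88,0.9957,139.54,349.74,225.05,319.83,152.96,20.03,2.94,82.61,166.02,85.86,4.09,606.73,111.88,474.92,18.5,381.08
"D003",4.41,0.8512,144.09,213.21,218.13,550.75,55.39,344.7,79.94,202.34,201.65,477.33,72.01,65.86,519.61,167.49,465.77,143.19
"D004",4.08,1.588,21.44,363.64,15.75,674.98,65.8,52.28,100.54,116.32,383.2,125.84,446.68,450.31,1423.31,91.27,194.27,381.64
"D005",3.33,1.1496,72.49,59.43,102.03,364.41,2.64,105.96,57.6,337.05,197.41,28.57,35.99,962.81,10.64,316.35,51.22,498.34
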