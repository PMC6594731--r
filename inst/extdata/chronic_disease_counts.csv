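disease,one,two,three_plus,total
arthritis,237.8,653.4,772.9,1665.1
asthma,28.4,69.9,236.1,339.7
back,95.6,204.7,550.0,853.7
cancer,15.9,53.1,121.8,191.9
copd,8.9,37.8,216.7,257.5
diabetes,57.3,146.5,373.1,573.0
cvd,389.1,701.6,834.9,1920.5
mental,43.0,134.1,402.4,584.4
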