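{"genotype":"corrected","div_range":[4,42],"trajectories":{"pct_active_electrodes":{"div":[4,8,12,37,42],"value":[9,21.08,59.83615385,97.1,95]},"spike_rate":{"div":[4,12,15,17,25,38,42],"value":[0.17094017,1.20843305,4.3,4.76190476,15.02,14.21395413,4.37]},"burst_rate":{"div":[4,12,13,14,15,16,17,18,19,20,21,22,23,24,25,26,27,28,29,30,31,32,33,34,35,36,37,38,39,40,41,42],"value":[1.228,3.812,4.71452991,5.62847222,6.54842105,6.57295876,6.5350303,6.43834653,6.2863301,6.08214286,5.82871028,5.52874312,5.18475676,4.7990885,4.37391304,4.80566978,5.2453092,5.69210526,6.14541844,6.6046832,7.06939759,7.53911458,8.01343473,8.492,8.17792304,7.84689617,7.49673487,7.12486239,6.72821755,6.30313535,5.84519027,5.34898829]},"burst_duration":{"div":[4,10,12,15,25,34,42],"value":[0.06,0.09,0.5,0.95,1.15,1.5,1.04333333]},"pct_spikes_in_bursts":{"div":[4,8,12,19,25,38,42],"value":[15,27,55,88.69,87,86,65]},"network_burst_rate":{"div":[4,8,9,15,25,34,42],"value":[0,0,0.8,3.09,1.3,1.9,1.79]},"network_burst_duration":{"div":[4,8,9,12,15,25,34,42],"value":[0,0,0.4,0.8,1.9,3.6,6.52,2.92222222]}}}
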