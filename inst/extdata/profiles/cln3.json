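{"genotype":"cln3","div_range":[4,42],"trajectories":{"pct_active_electrodes":{"div":[4,8,12,32,42],"value":[16,25.6,26.34,62.6,55]},"spike_rate":{"div":[4,7,12,42],"value":[0.33112583,1.63256535,2.27,2.45]},"burst_rate":{"div":[4,11,12,14,20,27,42],"value":[0.6325,7.53,7.4,4.5,3.3,2.9,2.9]},"burst_duration":{"div":[4,10,11,20,42],"value":[0.12,0.12,0.15,0.2,0.3]},"pct_spikes_in_bursts":{"div":[4,7,9,12,25,42],"value":[25,36.06,36.06,33.4,50.26,6.29]},"network_burst_rate":{"div":[4,8,9,15,24,30,42],"value":[0,0,0.1,0.25,1.24,0.46055556,0.1]},"network_burst_duration":{"div":[4,8,9,20,25,33,42],"value":[0,0,0.3,0.22375,0.8,2.42,1.2]}}}
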