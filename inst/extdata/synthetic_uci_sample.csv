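54.0,1,2,110.6,256.4,1,2,147.0,0,1.1,1,?,6,1
42.8,0,2,102.2,238.3,0,1,196.6,0,1.0,1,3,6,0
40.0,?,2,118.0,312.3,0,1,145.9,0,1.5,2,1,6,1
66.0,1,4,170.8,266.5,1,2,121.7,1,0.2,?,0,3,4
56.2,0,3,128.7,260.7,1,0,160.1,1,1.2,3,1,7,1
70.8,1,1,122.4,296.6,1,2,127.6,1,2.6,2,1,?,4
60.0,0,2,140.4,263.0,0,?,186.7,0,2.7,3,1,?,1
?,0,1,121.0,155.2,1,?,163.5,0,0.4,1,2,6,0
43.2,0,1,110.0,245.2,0,0,114.0,0,0.8,1,0,7,0
47.8,0,1,99.8,258.2,0,?,146.5,0,?,1,0,7,0
58.4,?,2,129.8,265.8,1,1,167.4,1,?,2,2,?,1
59.5,0,?,123.1,252.8,0,0,128.6,0,0.8,3,2,3,1
41.6,?,1,121.9,?,0,0,152.7,0,0.3,1,1,3,0
43.1,1,4,120.8,249.4,?,2,?,0,0.4,2,1,3,1
65.2,0,1,119.8,280.5,1,0,117.1,0,2.5,1,2,?,1
65.0,1,1,128.6,247.5,1,2,?,0,0.0,3,1,3,1
49.6,0,?,114.3,211.1,0,0,174.8,0,?,3,0,3,0
44.8,?,1,109.3,288.9,0,1,151.0,0,1.4,3,0,6,0
47.0,0,?,119.9,?,0,0,138.1,?,1.3,2,3,3,0
29.0,1,1,99.5,162.7,0,0,168.5,0,0.6,1,2,?,0
35.1,0,2,96.0,202.2,0,0,182.3,0,0.0,?,0,?,0
44.4,0,1,119.1,188.1,0,1,169.1,0,0.1,1,?,6,0
62.5,1,2,146.5,304.4,1,0,157.4,1,?,3,2,3,3
54.7,0,4,124.4,281.7,0,0,177.0,0,3.1,3,3,6,1
64.6,0,4,152.0,324.3,1,2,109.6,1,3.0,3,?,6,3
47.1,0,?,124.8,136.4,0,?,175.4,0,0.0,1,0,3,0
32.6,0,1,123.2,182.5,0,1,164.1,0,0.0,1,?,6,0
59.8,1,3,133.9,240.4,1,2,146.9,1,3.3,3,3,6,4
33.6,0,1,120.5,176.6,0,2,184.6,1,0.0,2,?,?,0
35.0,?,3,103.6,139.9,0,0,160.2,0,0.0,1,2,?,0
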