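country,lat,lon
Argentina,-34.6,-64.0
Australia,-25.0,134.0
Belgium,50.6,4.7
Brazil,-10.8,-53.1
Chile,-33.5,-70.7
Denmark,56.0,10.0
France,46.6,2.5
Germany,51.1,10.4
Greece,39.1,22.9
Hungary,47.2,19.4
Italy,42.8,12.1
Mexico,23.9,-102.5
Netherlands,52.2,5.3
New Zealand,-41.8,172.8
Portugal,39.6,-8.0
South Africa,-29.0,25.1
Spain,40.2,-3.6
UK,54.0,-2.0
Uruguay,-32.8,-56.0
USA,39.8,-98.6
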