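{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"role":"outer_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"outer_m1","mitochondrion_id":"m1"},"geometry":{"type":"Polygon","coordinates":[[[0,0],[40,0],[40,30],[0,30],[0,0]]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_1","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,2.8],[35,2.8]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_2","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,4.6],[35,4.6]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_3","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,6.4],[35,6.4]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_4","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,8.2],[35,8.2]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_5","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,10],[35,10]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_6","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,11.8],[35,11.8]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_7","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,13.6],[35,13.6]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_8","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,15.4],[35,15.4]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_9","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,17.2],[35,17.2]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_10","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,19],[35,19]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_11","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,20.8],[35,20.8]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_12","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,22.6],[35,22.6]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_13","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,24.4],[35,24.4]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_14","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,26.2],[35,26.2]]}},{"type":"Feature","properties":{"role":"inner_membrane","micrograph_id":"example_15000_1","magnification":15000,"object_id":"inner_m1_15","mitochondrion_id":"m1"},"geometry":{"type":"LineString","coordinates":[[5,28],[35,28]]}}]}
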