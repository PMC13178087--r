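{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"role":"interfibrillar","micrograph_id":"example_5000_1","magnification":5000,"object_id":"ifs_1"},"geometry":{"type":"Polygon","coordinates":[[[0,0],[200,0],[200,150],[0,150],[0,0]]]}},{"type":"Feature","properties":{"role":"mitochondrion","micrograph_id":"example_5000_1","magnification":5000,"object_id":"mito_1"},"geometry":{"type":"Polygon","coordinates":[[[20,20],[60,20],[60,50],[20,50],[20,20]]]}},{"type":"Feature","properties":{"role":"mitochondrion","micrograph_id":"example_5000_1","magnification":5000,"object_id":"mito_2"},"geometry":{"type":"Polygon","coordinates":[[[100,60],[150,60],[150,120],[100,120],[100,60]]]}},{"type":"Feature","properties":{"role":"mitochondrion","micrograph_id":"example_5000_1","magnification":5000,"object_id":"mito_3"},"geometry":{"type":"Polygon","coordinates":[[[30,80],[80,80],[55,130],[30,80]]]}}]}
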