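{"type":"Feature","properties":{"crs":"ETRS89-geographic"},"geometry":{"type":"Polygon","coordinates":[[[12,44.8],[13.5,45.6],[16,44.9],[18.5,42.5],[19.5,40.5],[18,40],[15.5,41.5],[13,43.5],[12,44.8]]]}}
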