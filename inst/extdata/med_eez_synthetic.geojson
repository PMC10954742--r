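{
  "type": "FeatureCollection",
  "name": "med_eez_synthetic",
  "description": "Synthetic, heavily simplified Mediterranean EEZ stand-in polygons (WGS84 lon/lat), convex-hull grade, for testing and examples. Not the Marine Regions geodatabase.",
  "features": [
    {"type": "Feature", "properties": {"country": "IL"},
     "geometry": {"type": "Polygon", "coordinates": [[[33.6, 31.2], [35.1, 31.2], [35.1, 33.1], [33.6, 33.1], [33.6, 31.2]]]}},
    {"type": "Feature", "properties": {"country": "PS"},
     "geometry": {"type": "Polygon", "coordinates": [[[33.9, 31.0], [34.6, 31.0], [34.6, 31.9], [33.9, 31.9], [33.9, 31.0]]]}},
    {"type": "Feature", "properties": {"country": "LB"},
     "geometry": {"type": "Polygon", "coordinates": [[[34.6, 33.1], [35.9, 33.1], [35.9, 34.7], [34.6, 34.7], [34.6, 33.1]]]}},
    {"type": "Feature", "properties": {"country": "SY"},
     "geometry": {"type": "Polygon", "coordinates": [[[34.8, 34.7], [36.2, 34.7], [36.2, 35.9], [34.8, 35.9], [34.8, 34.7]]]}},
    {"type": "Feature", "properties": {"country": "CY"},
     "geometry": {"type": "Polygon", "coordinates": [[[31.8, 34.2], [34.8, 34.2], [34.8, 36.0], [31.8, 36.0], [31.8, 34.2]]]}},
    {"type": "Feature", "properties": {"country": "TR"},
     "geometry": {"type": "Polygon", "coordinates": [[[26.0, 35.7], [36.3, 35.7], [36.3, 36.9], [30.5, 36.9], [27.2, 38.8], [26.0, 38.8], [26.0, 35.7]]]}},
    {"type": "Feature", "properties": {"country": "EG"},
     "geometry": {"type": "Polygon", "coordinates": [[[25.0, 30.9], [34.2, 30.9], [34.2, 32.6], [25.0, 32.6], [25.0, 30.9]]]}},
    {"type": "Feature", "properties": {"country": "GR"},
     "geometry": {"type": "Polygon", "coordinates": [[[19.8, 34.6], [28.3, 34.6], [28.3, 40.5], [19.8, 40.5], [19.8, 34.6]]]}},
    {"type": "Feature", "properties": {"country": "LY"},
     "geometry": {"type": "Polygon", "coordinates": [[[11.5, 31.3], [25.0, 31.3], [25.0, 33.5], [11.5, 33.5], [11.5, 31.3]]]}},
    {"type": "Feature", "properties": {"country": "AL"},
     "geometry": {"type": "Polygon", "coordinates": [[[18.8, 39.6], [20.0, 39.6], [20.0, 42.0], [18.8, 42.0], [18.8, 39.6]]]}},
    {"type": "Feature", "properties": {"country": "ME"},
     "geometry": {"type": "Polygon", "coordinates": [[[18.3, 41.8], [19.4, 41.8], [19.4, 42.7], [18.3, 42.7], [18.3, 41.8]]]}},
    {"type": "Feature", "properties": {"country": "HR"},
     "geometry": {"type": "Polygon", "coordinates": [[[13.5, 42.3], [18.5, 42.3], [18.5, 45.5], [13.5, 45.5], [13.5, 42.3]]]}},
    {"type": "Feature", "properties": {"country": "IT"},
     "geometry": {"type": "Polygon", "coordinates": [[[8.0, 36.5], [18.6, 36.5], [18.6, 45.5], [12.5, 45.5], [12.5, 44.0], [8.0, 44.0], [8.0, 36.5]]]}},
    {"type": "Feature", "properties": {"country": "MT"},
     "geometry": {"type": "Polygon", "coordinates": [[[14.0, 35.7], [14.8, 35.7], [14.8, 36.2], [14.0, 36.2], [14.0, 35.7]]]}},
    {"type": "Feature", "properties": {"country": "TN"},
     "geometry": {"type": "Polygon", "coordinates": [[[7.8, 33.0], [11.6, 33.0], [11.6, 37.5], [7.8, 37.5], [7.8, 33.0]]]}},
    {"type": "Feature", "properties": {"country": "ES"},
     "geometry": {"type": "Polygon", "coordinates": [[[-5.5, 35.0], [4.5, 35.0], [4.5, 42.0], [-5.5, 42.0], [-5.5, 35.0]]]}},
    {"type": "Feature", "properties": {"country": "DZ"},
     "geometry": {"type": "Polygon", "coordinates": [[[-2.2, 35.0], [8.7, 35.0], [8.7, 37.5], [-2.2, 37.5], [-2.2, 35.0]]]}}
  ]
}
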