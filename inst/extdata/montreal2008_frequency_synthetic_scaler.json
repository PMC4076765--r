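{
 "model": "mvoprobit",
 "note": "Trivariate ordered probit coefficients as published for the Montreal 2008 OD survey senior subsample; variables printed '-' are structural exclusions. Transit cut points were published non-monotone and are stored sorted ascending. The identity coordinate_scaler is a synthetic placeholder; format/loading fixture only.",
 "schema": {
  "variables": {
   "age": {
    "type": "categorical",
    "levels": [
     "younger",
     "senior",
     "elder"
    ],
    "reference": "younger"
   },
   "gender": {
    "type": "categorical",
    "levels": [
     "female",
     "male"
    ],
    "reference": "female"
   },
   "household": {
    "type": "categorical",
    "levels": [
     "single",
     "couple",
     "other"
    ],
    "reference": "single"
   },
   "occupation": {
    "type": "categorical",
    "levels": [
     "retired",
     "fulltime",
     "parttime",
     "athome"
    ],
    "reference": "retired"
   },
   "income": {
    "type": "categorical",
    "levels": [
     "lt20k",
     "i20_40k",
     "i40_60k",
     "i60_80k",
     "i80_100k",
     "gt100k",
     "rfdk"
    ],
    "reference": "lt20k"
   },
   "licence": {
    "type": "categorical",
    "levels": [
     "no",
     "yes"
    ],
    "reference": "no"
   },
   "vehicles": {
    "type": "categorical",
    "levels": [
     "v0",
     "v1",
     "v2",
     "v3plus"
    ],
    "reference": "v0"
   },
   "pop_density": {
    "type": "categorical",
    "levels": [
     "low",
     "med",
     "high"
    ],
    "reference": "low"
   },
   "job_density": {
    "type": "categorical",
    "levels": [
     "low",
     "medium",
     "high"
    ],
    "reference": "low"
   },
   "street_density": {
    "type": "continuous"
   },
   "intersection_density": {
    "type": "continuous"
   },
   "bsf_to_da": {
    "type": "continuous"
   },
   "land_use_mix": {
    "type": "continuous"
   },
   "activity_locations_400m": {
    "type": "continuous"
   },
   "nearest_pharmacy": {
    "type": "continuous"
   },
   "nearest_health": {
    "type": "continuous"
   },
   "nearest_bank": {
    "type": "continuous"
   },
   "nearest_grocery": {
    "type": "continuous"
   },
   "nearest_library": {
    "type": "continuous"
   }
  }
 },
 "coordinate_scaler": {
  "center": [
   0,
   0
  ],
  "scale": [
   1,
   1
  ]
 },
 "coefs": {
  "walk": {
   "age:senior": -0.09,
   "age:elder": -0.1278,
   "household:couple": -0.073,
   "household:other": -0.1182,
   "occupation:fulltime": -0.363,
   "occupation:parttime": -0.1415,
   "income:i40_60k": -0.0763,
   "income:i80_100k": 0.1077,
   "income:gt100k": 0.1099,
   "licence:yes": -0.212,
   "vehicles:v1": -0.3919,
   "vehicles:v2": -0.6307,
   "vehicles:v3plus": -0.6145,
   "job_density:medium": -0.1199,
   "job_density:high": -0.3352,
   "street_density": 0.0039,
   "bsf_to_da": 0.2426,
   "activity_locations_400m": 0.115,
   "nearest_bank": -0.1425,
   "trend_y": -1.6413,
   "trend_x": -0.6904,
   "trend_y2": 0.2335,
   "trend_x2": 0.3873,
   "cbd_km": -1.164
  },
  "car": {
   "age:senior": 0.0864,
   "age:elder": 0.1375,
   "gender:male": -0.0748,
   "household:couple": -0.103,
   "household:other": -0.2213,
   "occupation:fulltime": -0.0725,
   "income:i40_60k": 0.1444,
   "income:i60_80k": 0.1729,
   "income:i80_100k": 0.0899,
   "income:gt100k": 0.2007,
   "licence:yes": 0.4791,
   "vehicles:v1": 1.4216,
   "vehicles:v2": 1.6987,
   "vehicles:v3plus": 1.6615,
   "pop_density:high": -0.0456,
   "job_density:medium": -0.0569,
   "job_density:high": -0.5265,
   "street_density": -0.0049,
   "bsf_to_da": -0.361,
   "activity_locations_400m": -0.07574,
   "nearest_grocery": 0.0679,
   "trend_y": 0.0885,
   "trend_x2": -0.0318,
   "cbd_km": 0.1558
  },
  "transit": {
   "age:senior": -0.0611,
   "age:elder": -0.2368,
   "gender:male": 0.0975,
   "household:couple": 0.0527,
   "household:other": 0.2155,
   "occupation:fulltime": 0.2961,
   "occupation:parttime": 0.2341,
   "income:i20_40k": 0.1242,
   "income:i60_80k": 0.0918,
   "income:gt100k": -0.1051,
   "licence:yes": -0.3722,
   "vehicles:v1": -1.0726,
   "vehicles:v2": -1.4726,
   "vehicles:v3plus": -1.5867,
   "job_density:medium": 0.2988,
   "job_density:high": 0.9346,
   "street_density": 0.0096,
   "intersection_density": -0.0009,
   "activity_locations_400m": -0.1078,
   "nearest_pharmacy": -0.086,
   "nearest_health": -0.1703,
   "nearest_bank": 0.0596,
   "trend_y": 0.5818,
   "trend_y2": -0.1214
  }
 },
 "thresholds": {
  "walk": [
   -3.5794,
   -3.4745,
   -2.2748
  ],
  "car": [
   0.9163,
   1.0759,
   3.0781
  ],
  "transit": [
   -0.9343,
   -0.747,
   2.7782
  ]
 },
 "corr": [
  [
   1,
   -0.474,
   -0.231
  ],
  [
   -0.474,
   1,
   -0.656
  ],
  [
   -0.231,
   -0.656,
   1
  ]
 ]
}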