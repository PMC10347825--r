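{
  "name": "Published six-factor EPL scoring system",
  "B": 0.46,
  "factors": [
    {
      "name": "ma", "beta": 0.0920, "deviation_mode": "signed",
      "categories": [
        {"label": "<29",   "upper": 30,   "upper_closed": false, "representative": 26.0, "is_base": false},
        {"label": "30-39", "upper": 40,   "upper_closed": false, "representative": 34.5, "is_base": true},
        {"label": ">=40",  "upper": null, "upper_closed": false, "representative": 42.0, "is_base": false}
      ]
    },
    {
      "name": "gsd", "beta": -0.1150, "deviation_mode": "signed",
      "categories": [
        {"label": "<9.0",      "upper": 9,    "upper_closed": false, "representative": 6.2,  "is_base": false},
        {"label": "9.0-12.9",  "upper": 13,   "upper_closed": false, "representative": 11.0, "is_base": false},
        {"label": "13.0-27.0", "upper": 27,   "upper_closed": true,  "representative": 19.0, "is_base": true},
        {"label": ">27.0",     "upper": null, "upper_closed": false, "representative": 27.3, "is_base": false}
      ]
    },
    {
      "name": "el", "beta": -0.2450, "deviation_mode": "signed",
      "categories": [
        {"label": "<2.0",    "upper": 2,    "upper_closed": false, "representative": 1.0, "is_base": false},
        {"label": "2.1-6.3", "upper": 6.3,  "upper_closed": true,  "representative": 4.2, "is_base": true},
        {"label": ">6.3",    "upper": null, "upper_closed": false, "representative": 6.5, "is_base": false}
      ]
    },
    {
      "name": "ehr", "beta": -0.0340, "deviation_mode": "signed",
      "categories": [
        {"label": "<100",    "upper": 100,  "upper_closed": false, "representative": 50.0,  "is_base": false},
        {"label": "100-130", "upper": 130,  "upper_closed": false, "representative": 115.0, "is_base": true},
        {"label": ">=130",   "upper": null, "upper_closed": false, "representative": 140.0, "is_base": false}
      ]
    },
    {
      "name": "ysd", "beta": -0.1590, "deviation_mode": "absolute",
      "categories": [
        {"label": "<3.00",     "upper": 3,    "upper_closed": false, "representative": 1.5, "is_base": false},
        {"label": "3.00-4.99", "upper": 5,    "upper_closed": false, "representative": 4.0, "is_base": true},
        {"label": ">=5.00",    "upper": null, "upper_closed": false, "representative": 6.0, "is_base": false}
      ]
    },
    {
      "name": "em", "beta": -0.074, "deviation_mode": "signed",
      "categories": [
        {"label": "<10.0",      "upper": 10,   "upper_closed": false, "representative": 5.0,  "is_base": false},
        {"label": "10.0-14.99", "upper": 15,   "upper_closed": false, "representative": 12.5, "is_base": true},
        {"label": ">=15.0",     "upper": null, "upper_closed": false, "representative": 16.3, "is_base": false}
      ]
    }
  ],
  "risk_table": {
    "total": [-8, -7, -6, -5, -4, -3, -2, -1, 0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14],
    "risk": [0.18, 0.24, 0.31, 0.54, 0.81, 1.24, 1.85, 2.84, 4.20, 7.33, 11.02, 15.57, 22.03, 30.03, 39.55, 50.59, 60.50, 70.67, 78.54, 84.90, 89.51, 92.65, 95.42]
  }
}
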