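{
  "description": "PowerPlex-16-style panel fixture. Allele lists follow the public PowerPlex 16 allelic ladder composition, with FGA trimmed to 28 alleles so the ladder totals exactly 210 fragments. Nominal sizes are representative amplicon coordinates, not vendor-exact values.",
  "dyes": [
    {
      "name": "FL",
      "detectorIndex": 1
    },
    {
      "name": "JOE",
      "detectorIndex": 2
    },
    {
      "name": "TMR",
      "detectorIndex": 3
    },
    {
      "name": "CXR",
      "detectorIndex": 4
    }
  ],
  "loci": [
    {
      "name": "D3S1358",
      "dye": "FL",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["12", "13", "14", "15", "16", "17", "18", "19"],
        "size": [115, 119, 123, 127, 131, 135, 139, 143]
      }
    },
    {
      "name": "TH01",
      "dye": "FL",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["4", "5", "6", "7", "8", "9", "9.3", "10", "11", "13.3"],
        "size": [156, 160, 164, 168, 172, 176, 179, 180, 184, 195]
      }
    },
    {
      "name": "D21S11",
      "dye": "FL",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["24", "24.2", "25", "26", "27", "28", "28.2", "29", "29.2", "30", "30.2", "31", "31.2", "32", "32.2", "33", "33.2", "34", "34.2", "35", "35.2", "36", "37", "38"],
        "size": [203, 205, 207, 211, 215, 219, 221, 223, 225, 227, 229, 231, 233, 235, 237, 239, 241, 243, 245, 247, 249, 251, 255, 259]
      }
    },
    {
      "name": "D18S51",
      "dye": "FL",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["8", "9", "10", "10.2", "11", "12", "13", "13.2", "14", "14.2", "15", "16", "17", "18", "19", "20", "21", "22", "23", "24", "25", "26", "27"],
        "size": [290, 294, 298, 300, 302, 306, 310, 312, 314, 316, 318, 322, 326, 330, 334, 338, 342, 346, 350, 354, 358, 362, 366]
      }
    },
    {
      "name": "PentaE",
      "dye": "FL",
      "repeatUnit": 5,
      "stutterThreshold": 0.15,
      "isCodis": false,
      "ladder": {
        "allele": ["5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18", "19", "20", "21", "22", "23", "24"],
        "size": [379, 384, 389, 394, 399, 404, 409, 414, 419, 424, 429, 434, 439, 444, 449, 454, 459, 464, 469, 474]
      }
    },
    {
      "name": "D5S818",
      "dye": "JOE",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["7", "8", "9", "10", "11", "12", "13", "14", "15", "16"],
        "size": [119, 123, 127, 131, 135, 139, 143, 147, 151, 155]
      }
    },
    {
      "name": "D13S317",
      "dye": "JOE",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["7", "8", "9", "10", "11", "12", "13", "14", "15"],
        "size": [176, 180, 184, 188, 192, 196, 200, 204, 208]
      }
    },
    {
      "name": "D7S820",
      "dye": "JOE",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["6", "7", "8", "9", "10", "11", "12", "13", "14"],
        "size": [215, 219, 223, 227, 231, 235, 239, 243, 247]
      }
    },
    {
      "name": "D16S539",
      "dye": "JOE",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["5", "8", "9", "10", "11", "12", "13", "14", "15"],
        "size": [264, 276, 280, 284, 288, 292, 296, 300, 304]
      }
    },
    {
      "name": "CSF1PO",
      "dye": "JOE",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["6", "7", "8", "9", "10", "11", "12", "13", "14", "15"],
        "size": [321, 325, 329, 333, 337, 341, 345, 349, 353, 357]
      }
    },
    {
      "name": "PentaD",
      "dye": "JOE",
      "repeatUnit": 5,
      "stutterThreshold": 0.15,
      "isCodis": false,
      "ladder": {
        "allele": ["2.2", "3.2", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17"],
        "size": [378, 383, 391, 396, 401, 406, 411, 416, 421, 426, 431, 436, 441, 446, 451]
      }
    },
    {
      "name": "Amelogenin",
      "dye": "TMR",
      "repeatUnit": 6,
      "stutterThreshold": 0.15,
      "isCodis": false,
      "ladder": {
        "allele": ["X", "Y"],
        "size": [106, 112]
      }
    },
    {
      "name": "vWA",
      "dye": "TMR",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["10", "11", "12", "13", "14", "15", "16", "17", "18", "19", "20", "21", "22"],
        "size": [123, 127, 131, 135, 139, 143, 147, 151, 155, 159, 163, 167, 171]
      }
    },
    {
      "name": "D8S1179",
      "dye": "TMR",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18"],
        "size": [203, 207, 211, 215, 219, 223, 227, 231, 235, 239, 243, 247]
      }
    },
    {
      "name": "TPOX",
      "dye": "TMR",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["6", "7", "8", "9", "10", "11", "12", "13"],
        "size": [262, 266, 270, 274, 278, 282, 286, 290]
      }
    },
    {
      "name": "FGA",
      "dye": "TMR",
      "repeatUnit": 4,
      "stutterThreshold": 0.15,
      "isCodis": true,
      "ladder": {
        "allele": ["16", "17", "18", "18.2", "19", "19.2", "20", "20.2", "21", "21.2", "22", "22.2", "23", "23.2", "24", "24.2", "25", "25.2", "26", "26.2", "27", "28", "29", "30", "42.2", "43.2", "44.2", "45.2"],
        "size": [308, 312, 316, 318, 320, 322, 324, 326, 328, 330, 332, 334, 336, 338, 340, 342, 344, 346, 348, 350, 352, 356, 360, 364, 414, 418, 422, 426]
      }
    }
  ],
  "ils": {
    "dye": "CXR",
    "fragmentSizes": [60, 80, 100, 120, 140, 160, 180, 200, 230, 260, 290, 320, 350, 380, 410, 440, 470, 500, 550, 600]
  },
  "analyticalThreshold": 100,
  "phrThreshold": 0.3,
  "binHalfWidth": 0.5,
  "sizingRange": [100, 500]
}
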