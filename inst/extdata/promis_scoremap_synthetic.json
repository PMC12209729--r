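{
  "note": "SYNTHETIC raw-to-T tables for testing and examples only. Item groupings follow the published Global Health v1.2 and Pain Interference 8a structure; the T-score values are NOT the licensed conversion tables. Supply the licensed tables via read_score_map() for real scoring.",
  "constructs": {
    "physical_health": ["g03", "g06", "g07", "g08"],
    "mental_health": ["g02", "g04", "g05", "g10"],
    "pain_interference": ["pi1", "pi2", "pi3", "pi4", "pi5", "pi6", "pi7", "pi8"]
  },
  "recodes": {
    "g07": {
      "1": 5,
      "2": 4,
      "3": 3,
      "4": 2,
      "5": 1
    },
    "g08": {
      "1": 5,
      "2": 4,
      "3": 3,
      "4": 2,
      "5": 1
    }
  },
  "raw_to_t": {
    "physical_health": {
      "4": 16.2,
      "5": 19.4,
      "6": 22.6,
      "7": 25.8,
      "8": 29,
      "9": 32.2,
      "10": 35.4,
      "11": 38.6,
      "12": 41.8,
      "13": 45,
      "14": 48.2,
      "15": 51.4,
      "16": 54.6,
      "17": 57.8,
      "18": 61,
      "19": 64.2,
      "20": 67.4
    },
    "mental_health": {
      "4": 17.1,
      "5": 20.2,
      "6": 23.3,
      "7": 26.4,
      "8": 29.5,
      "9": 32.6,
      "10": 35.7,
      "11": 38.8,
      "12": 41.9,
      "13": 45,
      "14": 48.1,
      "15": 51.2,
      "16": 54.3,
      "17": 57.4,
      "18": 60.5,
      "19": 63.6,
      "20": 66.7
    },
    "pain_interference": {
      "8": 41.6,
      "9": 42.7,
      "10": 43.8,
      "11": 44.9,
      "12": 46,
      "13": 47.1,
      "14": 48.2,
      "15": 49.3,
      "16": 50.4,
      "17": 51.5,
      "18": 52.6,
      "19": 53.7,
      "20": 54.8,
      "21": 55.9,
      "22": 57,
      "23": 58.1,
      "24": 59.2,
      "25": 60.3,
      "26": 61.4,
      "27": 62.5,
      "28": 63.6,
      "29": 64.7,
      "30": 65.8,
      "31": 66.9,
      "32": 68,
      "33": 69.1,
      "34": 70.2,
      "35": 71.3,
      "36": 72.4,
      "37": 73.5,
      "38": 74.6,
      "39": 75.7,
      "40": 76.8
    }
  }
}
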