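{
  "_comment": "SYNTHETIC fixture. Shaped like a two-dated-unit collection (two analysis units with two radiocarbon dates each plus one undated unit, no recorded stratigraphic order); all ages and lab ids are invented.",
  "collectionunit": {
    "id": "CU-SYN-1",
    "site": "Synthetic Rockshelter",
    "declared_order": null,
    "analysis_units": [
      {
        "id": "101",
        "name": "upper stratum (synthetic)",
        "depth": null,
        "dates": [
          {"lab_id": "SYN-0001", "kind": "radiocarbon", "age": 10000, "error_minus": 150},
          {"lab_id": "SYN-0002", "kind": "radiocarbon", "age": 10200, "error_minus": 120}
        ]
      },
      {
        "id": "102",
        "name": "undated lens (synthetic)",
        "depth": null,
        "dates": []
      },
      {
        "id": "103",
        "name": "lower stratum (synthetic)",
        "depth": null,
        "dates": [
          {"lab_id": "SYN-0003", "kind": "radiocarbon", "age": 15000, "error_minus": 200},
          {"lab_id": "SYN-0004", "kind": "radiocarbon", "age": 16500, "error_minus": 250}
        ]
      }
    ]
  }
}
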