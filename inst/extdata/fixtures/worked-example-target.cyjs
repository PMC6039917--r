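{
  "format_version": "1.0",
  "data": { "name": "worked-example-target" },
  "elements": {
    "nodes": [
      { "data": { "id": 1, "name": "A", "selected": false }, "position": { "x": 13,  "y": 310 } },
      { "data": { "id": 2, "name": "B", "selected": false }, "position": { "x": 177, "y": 25 } },
      { "data": { "id": 3, "name": "C", "selected": false }, "position": { "x": 52,  "y": 140 } },
      { "data": { "id": 4, "name": "D", "selected": false }, "position": { "x": 301, "y": 88 } },
      { "data": { "id": 5, "name": "E", "selected": false }, "position": { "x": 225, "y": 260 } },
      { "data": { "id": 6, "name": "F", "selected": false }, "position": { "x": 90,  "y": 45 } },
      { "data": { "id": 7, "name": "G", "selected": false }, "position": { "x": 160, "y": 199 } },
      { "data": { "id": 8, "name": "N", "selected": false }, "position": { "x": 275, "y": 330 } },
      { "data": { "id": 9, "name": "O", "selected": false }, "position": { "x": 340, "y": 210 } }
    ],
    "edges": [
      { "data": { "source": 1, "target": 2, "interaction": "pp" } },
      { "data": { "source": 2, "target": 3, "interaction": "pp" } },
      { "data": { "source": 4, "target": 5, "interaction": "pp" } },
      { "data": { "source": 5, "target": 8, "interaction": "pp" } },
      { "data": { "source": 8, "target": 9, "interaction": "pp" } },
      { "data": { "source": 7, "target": 9, "interaction": "pp" } }
    ]
  }
}
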