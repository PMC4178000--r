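site_id,year,chevron_count,camera_snapshot_hits,depth_m,lat_deg,temp_c,livebot,hardsub,relief,soak_min,cdir,cspeed,turb
RS-001,2010,2,5,18.5,27.81,24.1,m,h,m,88,toward,low,low
RS-002,2010,0,0,42.0,28.40,22.6,l,l,l,91,perpendicular,high,low
RS-003,2010,0,3,35.5,29.02,23.0,h,m,h,95,away,low,high
RS-004,2011,1,0,55.0,29.77,21.2,m,m,l,87,toward,low,low
RS-005,2011,0,0,71.5,30.54,19.8,l,l,m,90,perpendicular,high,low
RS-006,2011,0,8,24.0,31.20,23.4,m,h,h,93,away,high,high
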